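# Normal-mode analysis and off-equilibrium sampling: stencils, mode
# counting, energy partition, displacements, Z-matrix application.

test_that("FD Hessian matches the analytic oracle and the diatomic
          closed form", {
  fx <- opt_conformer("O", polish = TRUE)
  fd <- finite_difference_hessian(fx$conf$structure, fx$ff)
  Ha <- analytic_hessian(fx$ff, fx$conf$structure)
  expect_lt(max(abs(fd$H - Ha)), 1e-6)
  # symmetrization residual is tiny at a genuine minimum
  expect_lt(max(abs(fd$H - t(fd$H))), 1e-6)
  # translation null space
  n3 <- nrow(fd$H)
  tx <- rep(c(1, 0, 0), n3 / 3)
  expect_lt(max(abs(fd$H %*% tx)), 1e-6)

  # diatomic: single internal mode with k = k_b / mu in the
  # mass-weighted convention
  g <- parse_smiles("N#N")
  ff <- toy_forcefield(g)
  r0 <- ff$bterms$r0[1L]
  s <- structure3d(c(7L, 7L), matrix(c(0, 0, 0, r0, 0, 0), 2L,
                                     byrow = TRUE))
  fd2 <- finite_difference_hessian(s, ff)
  m <- element_mass("N")
  nm <- normal_mode_analysis(fd2$H, rep(m, 2L), s)
  expect_identical(nm$n_f, 1L)
  mu <- m / 2
  expect_equal(nm$k, ff$bterms$kb[1L] / mu, tolerance = 1e-6)
})

test_that("saddle check accepts minima and rejects saddles", {
  fx <- opt_conformer("O", polish = TRUE)
  fd <- finite_difference_hessian(fx$conf$structure, fx$ff)
  expect_true(saddle_point_check(fd$stencil_energies, fd$E0))
  # 1D double well E = -x^2 + x^4: x = 0 is a saddle (maximum)
  h <- 1e-3
  E <- function(x) -x^2 + x^4
  se <- matrix(E(c(-3, -2, -1, 1, 2, 3) * h), 1L)
  expect_false(saddle_point_check(se, E(0)))
  # flat direction fails the strict-increase rule
  expect_false(saddle_point_check(matrix(rep(0, 6L), 1L), 0))
})

test_that("mode counting follows 3N-6 / 3N-5", {
  water <- opt_conformer("O", polish = TRUE)
  fdw <- finite_difference_hessian(water$conf$structure, water$ff)
  nmw <- normal_mode_analysis(fdw$H,
                              element_mass(element_symbol(
                                water$conf$structure$numbers)),
                              water$conf$structure)
  expect_identical(nmw$n_f, 3L)
  expect_false(nmw$linear)

  co2 <- opt_conformer("O=C=O", polish = TRUE)
  fdc <- finite_difference_hessian(co2$conf$structure, co2$ff)
  nmc <- normal_mode_analysis(fdc$H,
                              element_mass(element_symbol(
                                co2$conf$structure$numbers)),
                              co2$conf$structure)
  expect_identical(nmc$n_f, 4L)
  expect_true(nmc$linear)

  # orthonormality of retained modes
  for (nm in list(nmw, nmc)) {
    gram <- t(nm$modes) %*% nm$modes
    expect_lt(max(abs(gram - diag(nm$n_f))), 1e-8)
  }
})

test_that("temperature draw and equipartition energy", {
  set.seed(1)
  d0 <- draw_sample_energy(5L, T_max = 0)
  expect_identical(d0$E, 0)
  kB <- forge_constants$k_B
  set.seed(2)
  d <- draw_sample_energy(12L)
  expect_equal(d$E, 0.5 * 12 * kB * d$T, tolerance = 1e-14)
  expect_equal(0.5 * 12 * kB * 1000, 0.517, tolerance = 0.01)
  # Monte-Carlo mean: E[E] = n_f kB T_max / 4
  set.seed(3)
  es <- replicate(1e5, draw_sample_energy(3L)$E)
  expect_equal(mean(es), 3 * kB * 1000 / 4, tolerance = 0.01)
})

test_that("energy partition conserves exactly and is exchangeable", {
  set.seed(4)
  p0 <- partition_energy(0, 5L)
  expect_identical(p0$E_vec, rep(0, 5L))
  p1 <- partition_energy(0.7, 1L)
  expect_identical(p1$E_vec, 0.7)
  for (k in 1:200) {
    E <- stats::runif(1, 0, 2)
    p <- partition_energy(E, 7L)
    expect_identical(sum(p$E_vec), E)     # exact by construction
    expect_true(all(p$E_vec >= 0))
  }
  # per-mode expectation E/n_f by symmetry
  set.seed(5)
  m <- rowMeans(replicate(1e5, partition_energy(1, 5L)$E_vec))
  expect_equal(m, rep(0.2, 5L), tolerance = 0.02)
})

test_that("mode displacements follow the harmonic identity", {
  expect_equal(mode_displacements(0.5 * 2.3, 2.3, 1), 1)
  expect_identical(mode_displacements(0, 1, -1), 0)
  expect_identical(sign(mode_displacements(c(1, 1), c(2, 2), c(-3, 3))),
                   c(-1, 1))
  expect_error(mode_displacements(1, -1, 1), "force constant")
})

test_that("applying displacements: zero, diatomic closed form, zmatrix
          torsion", {
  g <- parse_smiles("N#N")
  ff <- toy_forcefield(g)
  r0 <- ff$bterms$r0[1L]
  s <- structure3d(c(7L, 7L), matrix(c(0, 0, 0, r0, 0, 0), 2L,
                                     byrow = TRUE))
  fd <- finite_difference_hessian(s, ff)
  m <- element_mass("N")
  nm <- normal_mode_analysis(fd$H, rep(m, 2L), s)

  s0 <- apply_displacements(nm, 0, mode = "cartesian")
  expect_equal(s0$positions, s$positions, tolerance = 1e-14)

  # bond length changes by delta / sqrt(mu) in the mass-weighted
  # convention
  delta <- 0.2
  s1 <- apply_displacements(nm, delta, mode = "cartesian")
  r1 <- sqrt(sum((s1$positions[2L, ] - s1$positions[1L, ])^2))
  mu <- m / 2
  expect_equal(abs(r1 - r0), delta / sqrt(mu), tolerance = 1e-10)

  # an exactly pure torsion mode in zmatrix mode changes only dihedrals:
  # rotate the hydroxyl hydrogen about the C-O axis of ethanol
  fe <- opt_conformer("CCO", polish = TRUE)
  se <- fe$conf$structure
  masses <- element_mass(element_symbol(se$numbers))
  x <- se$positions
  hO <- 9L; iO <- 3L; iC <- 2L       # explicit-atom ordering: C C O H...H
  axis <- (x[iO, ] - x[iC, ]) / sqrt(sum((x[iO, ] - x[iC, ])^2))
  vel <- c(axis[2] * (x[hO, 3] - x[iO, 3]) - axis[3] * (x[hO, 2] - x[iO, 2]),
           axis[3] * (x[hO, 1] - x[iO, 1]) - axis[1] * (x[hO, 3] - x[iO, 3]),
           axis[1] * (x[hO, 2] - x[iO, 2]) - axis[2] * (x[hO, 1] - x[iO, 1]))
  q <- rep(0, 3L * nrow(x))
  q[(3L * hO - 2L):(3L * hO)] <- vel * sqrt(masses[hO])  # mass-weighted
  q <- q / sqrt(sum(q^2))
  nm_pure <- structure(list(modes = matrix(q, ncol = 1L), k = 1,
                            n_f = 1L, linear = FALSE, masses = masses,
                            equilibrium = se), class = "normal_modes")
  st <- apply_displacements(nm_pure, 0.4, mode = "zmatrix")
  expect_identical(attr(st, "coordinate_system"), "zmatrix")
  zt <- zmatrix_topology(se)
  z0 <- zmatrix_coords(zt, se$positions)
  z1 <- zmatrix_coords(zt, st$positions)
  rsel <- seq(1L, length(z0), by = 3L)
  tsel <- seq(3L, length(z0), by = 3L)
  expect_lt(max(abs(z1[rsel] - z0[rsel]), na.rm = TRUE), 1e-4)  # bonds kept
  dphi <- abs(((z1[tsel] - z0[tsel] + 180) %% 360) - 180)
  expect_gt(max(dphi, na.rm = TRUE), 1)     # the dihedral actually moved
})

test_that("sampling orchestration: determinism, provenance, harmonic
          round trip", {
  fx <- opt_conformer("CCO", polish = TRUE)
  expect_identical(sample_offequilibrium(fx$conf, fx$ff, 0L), list())

  s1 <- sample_offequilibrium(fx$conf, fx$ff, 5L, seed = 31L)
  s2 <- sample_offequilibrium(fx$conf, fx$ff, 5L, seed = 31L)
  expect_identical(lapply(s1, `[[`, "positions"),
                   lapply(s2, `[[`, "positions"))
  d <- attr(s1[[1L]], "draw")
  expect_identical(sum(d$E_vec), d$E)
  expect_identical(sign(d$delta), sign(d$w))

  # exactly quadratic PES, Cartesian application: realized == drawn
  H <- analytic_hessian(fx$ff, fx$conf$structure)
  hc <- harmonic_calculator(fx$conf$structure$positions, H,
                            E0 = fx$conf$energy)
  samples <- sample_offequilibrium(fx$conf, hc, 50L, seed = 8L,
                                   mode = "cartesian")
  for (st in samples) {
    dE <- evaluate_calculator(hc, st, "energy")$energy - fx$conf$energy
    drawn <- attr(st, "draw")$E
    expect_equal(dE, drawn, tolerance = 1e-6 * max(drawn, 1e-12))
  }
})

test_that("saddle conformers are rejected by sampling", {
  # unpolished minimum: residual forces break the strict stencil
  # increase; this is exactly the filter doing its job
  g <- parse_smiles("N#N")
  ff <- toy_forcefield(g)
  r0 <- ff$bterms$r0[1L]
  # a deliberately displaced "conformer"
  s <- structure3d(c(7L, 7L), matrix(c(0, 0, 0, r0 + 0.05, 0, 0), 2L,
                                     byrow = TRUE))
  expect_error(sample_offequilibrium(s, ff, 3L), "rejected")
})
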