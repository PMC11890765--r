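# Calculator contract and the analytic toy force field.

test_that("toy diatomic behaves as a harmonic bond", {
  g <- parse_smiles("N#N")
  ff <- toy_forcefield(g)
  r0 <- ff$bterms$r0[1L]
  kb <- ff$bterms$kb[1L]
  well <- ff$params$well
  at <- function(r) structure3d(c(7L, 7L),
                                matrix(c(0, 0, 0, r, 0, 0), 2L,
                                       byrow = TRUE))
  r_eq <- evaluate_calculator(ff, at(r0), c("energy", "forces"))
  expect_equal(max(abs(r_eq$forces)), 0, tolerance = 1e-12)
  expect_equal(r_eq$energy, -well, tolerance = 1e-12)
  d <- 0.17
  r_st <- evaluate_calculator(ff, at(r0 + d), "energy")
  expect_equal(r_st$energy - r_eq$energy, 0.5 * kb * d^2, tolerance = 1e-10)
})

test_that("energy is invariant under rigid motion; net force is zero", {
  fx <- opt_conformer("CCO")
  s <- fx$conf$structure
  e0 <- evaluate_calculator(fx$ff, s, "energy")$energy
  for (sd in 1:3) {
    sp <- s
    sp$positions <- random_pose(s$positions, seed = sd)
    expect_equal(evaluate_calculator(fx$ff, sp, "energy")$energy, e0,
                 tolerance = 1e-9)
  }
  f <- evaluate_calculator(fx$ff, s, c("energy", "forces"))$forces
  expect_lt(max(abs(colSums(f))), 1e-10)  # translation invariance
})

test_that("forces are consistent with the energy for all calculators", {
  for (smi in c("O", "CCO")) {
    fx <- opt_conformer(smi)
    s <- fx$conf$structure
    s$positions <- s$positions + 0.05  # slightly off minimum
    expect_lt(check_force_consistency(fx$ff, s), 1e-4)
  }
  fx <- opt_conformer("O")
  hc <- harmonic_calculator(fx$conf$structure$positions,
                            analytic_hessian(fx$ff, fx$conf$structure))
  sp <- fx$conf$structure
  sp$positions <- sp$positions + 0.1
  expect_lt(check_force_consistency(hc, sp), 1e-4)
})

test_that("analytic Hessian matches the six-point finite difference", {
  fx <- opt_conformer("O", polish = TRUE)
  Ha <- analytic_hessian(fx$ff, fx$conf$structure)
  expect_equal(Ha, t(Ha))
  fd <- finite_difference_hessian(fx$conf$structure, fx$ff)
  expect_lt(max(abs(fd$H - Ha)), 1e-6)
  # Newton's third law: uniform translation is a null direction
  n <- length(fx$conf$structure$numbers)
  for (k in 1:3) {
    tvec <- rep(0, 3L * n)
    tvec[seq(k, 3L * n, by = 3L)] <- 1
    expect_lt(max(abs(Ha %*% tvec)), 1e-8)
  }
})

test_that("toy bond orders follow the distance-decay model", {
  g <- parse_smiles("N#N")
  ff <- toy_forcefield(g)
  r0 <- ff$bterms$r0[1L]
  alpha <- ff$params$alpha_bo
  at <- function(r) structure3d(c(7L, 7L),
                                matrix(c(0, 0, 0, r, 0, 0), 2L,
                                       byrow = TRUE))
  bo_eq <- toy_bond_orders(ff, at(r0))
  expect_equal(bo_eq[1L, 2L], 3, tolerance = 1e-12)   # nominal order
  expect_equal(bo_eq, t(bo_eq))
  expect_identical(diag(bo_eq), c(0, 0))
  # stretching by ln(4)/alpha quarters the bond order
  bo_st <- toy_bond_orders(ff, at(r0 + log(4) / alpha))
  expect_equal(bo_st[1L, 2L], 3 / 4, tolerance = 1e-12)
})

test_that("capability contract is enforced", {
  fx <- opt_conformer("O")
  hc <- harmonic_calculator(fx$conf$structure$positions,
                            analytic_hessian(fx$ff, fx$conf$structure))
  expect_error(evaluate_calculator(hc, fx$conf$structure, "bond_orders"),
               "lacks capabilities")
  expect_setequal(calculator_capabilities(fx$ff),
                  c("energy", "forces", "bond_orders", "partial_charges"))
})
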