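# Embedding, optimisation, rotatable bonds, symmetry-aware RMSD and
# deduplication.

test_that("embedding is deterministic and satisfies distance contracts", {
  g <- parse_smiles("C")
  s1 <- embed_initial(g, seed = 5L)
  s2 <- embed_initial(g, seed = 5L)
  expect_identical(s1$positions, s2$positions)
  # methane: 4 C-H distances near the covalent-radius sum
  dCH <- sqrt(rowSums((s1$positions[2:5, , drop = FALSE] -
                         matrix(s1$positions[1L, ], 4L, 3L,
                                byrow = TRUE))^2))
  r0 <- sum(covalent_radius(c("C", "H")))
  expect_true(all(abs(dCH - r0) < 0.3 * r0))
  # water is bent
  sw <- embed_initial(parse_smiles("O"), seed = 1L)
  v1 <- sw$positions[2L, ] - sw$positions[1L, ]
  v2 <- sw$positions[3L, ] - sw$positions[1L, ]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_lt(ang, 179)
  # minimum distance contract over a few molecules
  for (smi in c("CCO", "c1ccccc1", "CC(C)=O")) {
    s <- embed_initial(parse_smiles(smi), seed = 2L)
    d <- stats::dist(s$positions)
    expect_gt(min(d), 0.3)
  }
})

test_that("local optimization converges the harmonic diatomic", {
  g <- parse_smiles("N#N")
  ff <- toy_forcefield(g)
  r0 <- ff$bterms$r0[1L]
  s <- structure3d(c(7L, 7L), matrix(c(0, 0, 0, r0 + 0.3, 0, 0), 2L,
                                     byrow = TRUE))
  res <- local_optimize(s, ff)
  expect_true(res$converged)
  r_final <- sqrt(sum((res$structure$positions[2L, ] -
                         res$structure$positions[1L, ])^2))
  expect_lt(abs(r_final - r0), 1e-3)
  # already-converged input returns unchanged immediately
  res2 <- local_optimize(res$structure, ff)
  expect_identical(res2$steps, 0L)
  expect_identical(res2$structure$positions, res$structure$positions)
})

test_that("pre-optimization rescues overlapping starts", {
  g <- parse_smiles("CCO")
  ff <- toy_forcefield(g)
  s <- embed_initial(g, seed = 2L)
  # squash two atoms nearly on top of each other
  s$positions[4L, ] <- s$positions[5L, ] + 1e-3
  with_pre <- local_optimize(s, ff, pre_opt = TRUE)
  expect_true(with_pre$converged)
  expect_true(is_pes_minimum(ff, with_pre$structure))
})

test_that("rotatable bonds follow the ring and terminal rules", {
  rb <- find_rotatable_bonds(parse_smiles("CCO"))
  expect_identical(nrow(rb), 2L)       # C-C and C-O both rotatable
  expect_identical(nrow(find_rotatable_bonds(parse_smiles("C1CC1"))), 0L)
  rb6 <- find_rotatable_bonds(parse_smiles("C1CCCCC1"))
  expect_identical(nrow(rb6), 6L)
  expect_true(all(rb6$ring))
  # double bonds and bonds to bare halogens are not rotatable
  expect_identical(nrow(find_rotatable_bonds(parse_smiles("C=C"))), 0L)
  expect_identical(nrow(find_rotatable_bonds(parse_smiles("CF"))), 0L)
})

test_that("symmetry-aware RMSD never exceeds the naive RMSD", {
  fx <- opt_conformer("CCO")
  x <- fx$conf$structure$positions
  set.seed(9)
  for (k in 1:5) {
    y <- x + matrix(stats::rnorm(length(x), sd = 0.1), nrow(x), 3L)
    y <- random_pose(y, seed = k)
    expect_lte(symmetry_rmsd(x, y, fx$graph),
               kabsch_rmsd(x, y) + 1e-12)
  }
  # pose independence
  expect_lt(symmetry_rmsd(x, random_pose(x, seed = 3L), fx$graph), 1e-8)
})

test_that("deduplication collapses duplicates and mirror images", {
  fx <- opt_conformer("CCO")
  conf <- fx$conf
  expect_length(deduplicate(list(conf, conf, conf), fx$graph), 1L)

  # gauche(+)/gauche(-) butane pair: construct by torsion, reflect one
  g <- parse_smiles("CCCC")
  ff <- toy_forcefield(g)
  c0 <- local_optimize(embed_initial(g, seed = 3L), ff, pre_opt = TRUE)
  ex <- explicit_atoms(g)
  tr <- molforge:::.torsion_refs(ex)
  ccc <- which(tr$refs$a == 2L & tr$refs$b == 3L)
  x <- set_torsion(c0$structure$positions, tr$nbl, 2L, 3L,
                   tr$refs$ref_i[ccc], tr$refs$ref_j[ccc], 60)
  sg <- c0$structure; sg$positions <- x
  gp <- local_optimize(sg, ff)         # gauche(+)
  gm <- gp
  gm$structure$positions[, 3L] <- -gm$structure$positions[, 3L]  # mirror
  expect_length(deduplicate(list(gp, gm), g), 1L)
  expect_length(deduplicate(list(gp, gm), g, mirror = FALSE), 2L)
  # anti and gauche are distinct
  expect_length(deduplicate(list(c0, gp), g), 2L)
})

test_that("butane has two unique conformers (anti, gauche)", {
  g <- parse_smiles("CCCC")
  ff <- toy_forcefield(g)
  c0 <- local_optimize(embed_initial(g, seed = 4L), ff, pre_opt = TRUE)
  confs <- conformer_search(c0, ff, g, seed = 4L, generations = 6L)
  expect_length(confs, 2L)
  # every returned conformer meets the force contract and is a minimum
  for (cf in confs) {
    expect_lt(cf$fmax, forge_constants$f_max_opt)
    expect_lte(local_optimize(cf$structure, ff)$steps, 1L)
  }
})
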