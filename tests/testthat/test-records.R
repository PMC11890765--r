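# Record store, JSONL / extended-XYZ round trips, pipeline determinism.

test_that("hierarchy insert, children and dedup contracts", {
  st <- forge_store()
  gk <- put_graph(st, canonicalize("CCO"))
  gk2 <- put_graph(st, canonicalize("OCC"))
  expect_identical(gk, gk2)
  expect_length(st$graphs, 1L)

  s <- embed_initial(parse_smiles("CCO"), seed = 1L)
  ck1 <- put_conformation(st, gk, s)
  s2 <- s; s2$positions <- s2$positions + 0.5
  ck2 <- put_conformation(st, gk, s2)
  for (ck in c(ck1, ck2)) {
    for (m in 1:3) {
      sm <- s; sm$positions <- sm$positions + m
      sk <- put_conformation(st, gk, sm, "offequilibrium")
    }
  }
  expect_length(children(st, gk), 5L)

  put_calculation(st, ck1, "toy", list(energy = -1))
  expect_length(children(st, ck1), 1L)
  expect_error(put_calculation(st, "deadbeef", "toy", list(energy = 0)),
               "orphan")
  expect_error(put_conformation(st, "deadbeef", s), "orphan")
  expect_true(audit_store(st))
  # idempotent re-insert
  expect_identical(put_conformation(st, gk, s), ck1)
  expect_length(st$conformations, 5L)
})

test_that("JSONL round trip preserves fields and export units", {
  st <- forge_store()
  gk <- put_graph(st, "CCO")
  g <- parse_smiles("CCO")
  ff <- toy_forcefield(g)
  s <- embed_initial(g, seed = 2L)
  ck <- put_conformation(st, gk, s)
  r <- evaluate_calculator(ff, s, c("energy", "forces"))
  put_calculation(st, ck, "toy", list(energy = r$energy,
                                      forces = r$forces))
  d <- tempfile()
  export_jsonl(st, d)

  # exported positions are internal Angstrom / 0.529177210903
  line <- jsonlite::fromJSON(readLines(file.path(d,
                                                 "conformations.jsonl"))[1L])
  expect_equal(matrix(line$positions, ncol = 3L),
               s$positions / 0.529177210903, tolerance = 1e-12)
  expect_true(!is.null(line$key_hash))

  st2 <- import_jsonl(d)
  expect_identical(names(st2$graphs), names(st$graphs))
  c2 <- st2$conformations[[ck]]
  expect_equal(c2$positions, s$positions, tolerance = 1e-9)
  k2 <- st2$calculations[[names(st$calculations)[1L]]]
  expect_equal(k2$energy, r$energy, tolerance = 1e-12)
  expect_equal(k2$forces, r$forces, tolerance = 1e-9)

  # empty store exports valid empty files
  d2 <- tempfile()
  export_jsonl(forge_store(), d2)
  expect_true(file.exists(file.path(d2, "graphs.jsonl")))
  expect_length(import_jsonl(d2)$graphs, 0L)
})

test_that("extended XYZ round trip", {
  fx <- opt_conformer("O")
  s <- fx$conf$structure
  r <- evaluate_calculator(fx$ff, s, c("energy", "forces"))
  path <- tempfile(fileext = ".xyz")
  write_extxyz(list(s, s), path, forces = list(r$forces, r$forces),
               metadata = list(list(energy = r$energy, T = 300),
                               list(energy = r$energy, T = 400)))
  frames <- read_extxyz(path)
  expect_length(frames, 2L)
  expect_equal(frames[[1L]]$structure$positions, s$positions,
               tolerance = 1e-9)
  expect_identical(frames[[1L]]$structure$numbers, s$numbers)
  expect_equal(frames[[1L]]$forces, unname(r$forces), tolerance = 1e-9)
  expect_equal(as.numeric(frames[[2L]]$metadata$T), 400)
})

test_that("pipeline on a tiny config is deterministic and complete", {
  cfg <- forge_config("CO", seed = 5L, max_heavy = 2L, n_samples = 2L)
  st1 <- run_pipeline(cfg)
  st2 <- run_pipeline(cfg)
  # methanol seeds: amons give C and O as well
  smis <- sort(vapply(st1$graphs, `[[`, character(1), "canonical_smiles"))
  expect_setequal(smis, vapply(c("CO", "C", "O"), canonicalize,
                               character(1), USE.NAMES = FALSE))
  expect_identical(
    lapply(st1$conformations[order(names(st1$conformations))], `[[`,
           "positions"),
    lapply(st2$conformations[order(names(st2$conformations))], `[[`,
           "positions"))
  kinds <- table(vapply(st1$conformations, `[[`, character(1), "kind"))
  expect_identical(unname(kinds["offequilibrium"]),
                   2L * unname(kinds["conformer"]))
  expect_true(audit_store(st1))
  # every calculation has flags and finite energy
  for (cl in st1$calculations) {
    expect_true(is.finite(cl$energy))
    expect_false(is.null(cl$flags$is_outlier))
  }
})

test_that("max_heavy restricts the amon set in the pipeline", {
  cfg <- forge_config("CCO", seed = 5L, max_heavy = 2L, n_samples = 1L)
  st <- run_pipeline(cfg)
  hv <- vapply(st$graphs, `[[`, integer(1), "heavy_atom_count")
  # the seed itself stays recorded, but enrichment products obey the cap
  expect_true(all(hv[vapply(st$graphs, `[[`, character(1),
                            "provenance") == "enrichment"] <= 2L))
})
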