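# End-to-end pipeline: import/enrichment of chemical graphs, conformer
# generation, normal-mode sampling, calculation records with quality
# flags. Deterministic under a fixed seed; every stage logs counts and
# per-rejection reasons.

#' Default pipeline configuration
#'
#' @param seeds character vector of seed SMILES.
#' @param seed RNG seed for every stochastic stage.
#' @param max_heavy heavy-atom cutoff for downstream processing.
#' @param generators enrichment generators to run (any of "protonation",
#'   "stereo", "amons").
#' @param n_samples off-equilibrium samples per conformer; NULL uses the
#'   per-size schedule [sample_count_schedule()].
#' @param calculator calculator name; "toy" is packaged.
#' @param T_max sampling temperature ceiling (K).
#' @return config list.
#' @export
forge_config <- function(seeds, seed = 1L, max_heavy = 8L,
                         generators = c("protonation", "stereo", "amons"),
                         n_samples = NULL, calculator = "toy",
                         T_max = 1000) {
  list(seeds = seeds, seed = as.integer(seed), max_heavy = max_heavy,
       generators = generators, n_samples = n_samples,
       calculator = calculator, T_max = T_max)
}

.log_stage <- function(store, stage, ...) {
  store$log[[length(store$log) + 1L]] <- c(list(stage = stage), list(...))
}

#' Import SMILES into a store
#'
#' Sanitize, canonicalize, select enantiomer representatives, dedup.
#'
#' @param store forge_store.
#' @param smiles character vector.
#' @param provenance provenance tag.
#' @param max_heavy heavy-atom cutoff (graphs above it are kept in the
#'   graph store but marked; they are skipped by the 3D stages).
#' @return character vector of accepted canonical SMILES.
#' @export
import_smiles <- function(store, smiles, provenance = "import",
                          max_heavy = 8L) {
  accepted <- character(0)
  n_rej <- 0L
  for (s in smiles) {
    res <- tryCatch({
      cs <- canonicalize(sanitize(s))
      er <- enantiomer_representative(cs)
      if (!er$kept) "enantiomer_skipped" else er$smiles
    }, error = function(e) paste0("rejected: ", conditionMessage(e)))
    if (res %in% c("enantiomer_skipped") || startsWith(res, "rejected:")) {
      n_rej <- n_rej + 1L
      .log_stage(store, "import_reject", smiles = s, reason = res)
    } else {
      put_graph(store, res, provenance)
      accepted <- c(accepted, res)
    }
  }
  .log_stage(store, "import", n_in = length(smiles),
             n_accepted = length(accepted), n_rejected = n_rej)
  unique(accepted)
}

#' Run enrichment generators to a fixed point
#'
#' @param smiles canonical seed SMILES.
#' @param generators subset of "protonation", "stereo", "amons".
#' @param max_heavy heavy-atom cutoff applied to every product.
#' @return character vector of canonical SMILES (seeds included).
#' @export
enrich_fixed_point <- function(smiles,
                               generators = c("protonation", "stereo",
                                              "amons"),
                               max_heavy = 8L) {
  known <- unique(smiles)
  frontier <- known
  while (length(frontier) > 0L) {
    products <- character(0)
    for (s in frontier) {
      for (gen in generators) {
        p <- tryCatch(switch(gen,
          protonation = enumerate_protonation_states(s),
          stereo = enumerate_stereoisomers(s),
          amons = generate_amons(s, max_heavy = max_heavy)),
          error = function(e) character(0))
        products <- c(products, p)
      }
    }
    products <- filter_heavy_atoms(unique(products), max_heavy)
    frontier <- setdiff(products, known)
    known <- union(known, frontier)
  }
  sort(known)
}

#' Run the full pipeline
#'
#' @param config from [forge_config()].
#' @return forge_store with graphs, conformations (conformers and
#'   off-equilibrium samples) and flagged calculation records.
#' @export
run_pipeline <- function(config) {
  store <- forge_store()
  imported <- import_smiles(store, config$seeds, "seed",
                            config$max_heavy)
  enriched <- enrich_fixed_point(imported, config$generators,
                                 config$max_heavy)
  new_graphs <- setdiff(enriched, imported)
  for (s in new_graphs) {
    er <- enantiomer_representative(s)
    if (er$kept) put_graph(store, er$smiles, "enrichment")
  }
  .log_stage(store, "enrich", n_seeds = length(imported),
             n_total = length(enriched))

  todo <- Filter(function(r) r$heavy_atom_count <= config$max_heavy,
                 store$graphs)
  n_conf <- 0L; n_samp <- 0L; n_out <- 0L
  for (gr in todo) {
    g <- parse_smiles(gr$canonical_smiles)
    res <- tryCatch({
      ff <- toy_forcefield(g)
      s0 <- embed_initial(g, seed = config$seed)
      c0 <- local_optimize(s0, ff, pre_opt = TRUE)
      if (!c0$converged) stop("optimization did not converge")
      confs <- conformer_search(c0, ff, g, seed = config$seed)
      refs <- toy_reference_energies(unique(explicit_atoms(g)$elements))
      for (cf in confs) {
        # polish so the stencil saddle check is meaningful
        cf <- local_optimize(cf$structure, ff, f_max = 1e-6)
        bo <- toy_bond_orders(ff, cf$structure)
        if (!bond_order_consistency(kekulize(g), bo)) {
          .log_stage(store, "conformer_reject", graph = gr$key,
                     reason = "bond order inconsistent")
          next
        }
        ck <- put_conformation(store, gr$key, cf$structure, "conformer")
        n_conf <- n_conf + 1L
        ns <- if (is.null(config$n_samples))
          sample_count_schedule(gr$heavy_atom_count)
        else config$n_samples
        samples <- sample_offequilibrium(cf, ff, ns, config$T_max,
                                         seed = config$seed)
        for (st in samples) {
          sk <- put_conformation(store, gr$key, st, "offequilibrium",
                                 draw = attr(st, "draw"))
          r <- evaluate_calculator(ff, st,
                                   c("energy", "forces", "bond_orders",
                                     "partial_charges"))
          el <- element_symbol(st$numbers)
          fe <- formation_energy(r$energy, el, refs)
          flags <- flag_outlier(
            list(forces = r$forces, bond_orders = r$bond_orders,
                 formation_energy = fe),
            g, st)
          put_calculation(store, sk, config$calculator,
                          list(energy = r$energy, forces = r$forces,
                               bond_orders = r$bond_orders,
                               charges = r$charges,
                               formation_energy = fe, flags = flags))
          n_samp <- n_samp + 1L
          if (flags$is_outlier) n_out <- n_out + 1L
        }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res))
      .log_stage(store, "graph_skip", graph = gr$key, reason = res)
  }
  .log_stage(store, "pipeline", n_graphs = length(store$graphs),
             n_conformers = n_conf, n_samples = n_samp, n_outliers = n_out)
  audit_store(store)
  store
}
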