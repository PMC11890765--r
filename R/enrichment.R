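# Chemical-knowledge enrichment generators: protonation states,
# stereoisomers, amon subgraphs, and the heavy-atom restriction.

# --- shared graph-editing helpers -------------------------------------------

delete_atoms <- function(g, idx) {
  keep <- setdiff(seq_len(nrow(g$atoms)), idx)
  remap <- integer(nrow(g$atoms))
  remap[keep] <- seq_along(keep)
  g$atoms <- g$atoms[keep, , drop = FALSE]
  rownames(g$atoms) <- NULL
  kb <- !(g$bonds$i %in% idx | g$bonds$j %in% idx)
  g$bonds <- g$bonds[kb, , drop = FALSE]
  g$bonds$i <- remap[g$bonds$i]
  g$bonds$j <- remap[g$bonds$j]
  rownames(g$bonds) <- NULL
  g$stereo_atoms <- Filter(function(s) {
    all(c(s$atom, s$nbrs[s$nbrs > 0L]) %in% keep)
  }, g$stereo_atoms)
  g$stereo_atoms <- lapply(g$stereo_atoms, function(s) {
    s$atom <- remap[s$atom]
    s$nbrs <- ifelse(s$nbrs == 0L, 0L, remap[pmax(s$nbrs, 1L)])
    s
  })
  g$stereo_bonds <- Filter(function(s) {
    all(c(s$i, s$j, s$ref_i, s$ref_j) %in% keep)
  }, g$stereo_bonds)
  g$stereo_bonds <- lapply(g$stereo_bonds, function(s) {
    s$i <- remap[s$i]; s$j <- remap[s$j]
    s$ref_i <- remap[s$ref_i]; s$ref_j <- remap[s$ref_j]
    s
  })
  g
}

.bond_order_sum <- function(g) {
  n <- nrow(g$atoms)
  bsum <- numeric(n)
  for (k in seq_len(nrow(g$bonds))) {
    bsum[g$bonds$i[k]] <- bsum[g$bonds$i[k]] + g$bonds$order[k]
    bsum[g$bonds$j[k]] <- bsum[g$bonds$j[k]] + g$bonds$order[k]
  }
  bsum
}

graph_connected <- function(g) {
  n <- nrow(g$atoms)
  if (n <= 1L) return(TRUE)
  nb <- neighbour_list(g)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (u in nb[[v]]) if (!seen[u]) {
      seen[u] <- TRUE
      stack <- c(stack, u)
    }
  }
  all(seen)
}

# --- protonation states ------------------------------------------------------

# Rule table for (de)protonatable sites. Each rule identifies a site on the
# parsed graph and the two states it toggles between; the pH model of the
# reference workflow is replaced by this transparent, extensible table.
.protonation_sites <- function(g) {
  nb <- neighbour_list(g)
  bsum <- .bond_order_sum(g)
  el <- g$atoms$element
  sites <- list()
  is_carbonyl_c <- function(c) {
    any(vapply(nb[[c]], function(o)
      el[o] == "O" && bond_order_of(g, c, o) == 2, logical(1)))
  }
  for (v in seq_len(nrow(g$atoms))) {
    e <- el[v]; q <- g$atoms$charge[v]; h <- g$atoms$h[v]
    if (e == "O" && length(nb[[v]]) == 1L &&
        bond_order_of(g, v, nb[[v]][1L]) == 1 &&
        el[nb[[v]][1L]] == "C" && is_carbonyl_c(nb[[v]][1L])) {
      # carboxylic acid / carboxylate oxygen
      if ((q == 0L && h == 1L) || (q == -1L && h == 0L))
        sites[[length(sites) + 1L]] <- list(type = "acid_o", atom = v)
    } else if (e == "N" && !g$atoms$aromatic[v] &&
               all(vapply(nb[[v]], function(o)
                 bond_order_of(g, v, o) == 1, logical(1))) &&
               !any(vapply(nb[[v]], function(o)
                 el[o] == "C" && is_carbonyl_c(o), logical(1)))) {
      # amine <-> ammonium (amides excluded)
      if ((q == 0L && bsum[v] + h == 3) || (q == 1L && h >= 1L))
        sites[[length(sites) + 1L]] <- list(type = "amine_n", atom = v)
    } else if (e == "S" && length(nb[[v]]) == 1L &&
               bond_order_of(g, v, nb[[v]][1L]) == 1) {
      # thiol <-> thiolate
      if ((q == 0L && h == 1L) || (q == -1L && h == 0L))
        sites[[length(sites) + 1L]] <- list(type = "thiol_s", atom = v)
    }
  }
  sites
}

bond_order_of <- function(g, i, j) {
  k <- which((g$bonds$i == i & g$bonds$j == j) |
               (g$bonds$i == j & g$bonds$j == i))
  if (length(k) == 0L) return(0)
  g$bonds$order[k[1L]]
}

.apply_site_state <- function(g, site, state) {
  v <- site$atom
  if (site$type == "acid_o" || site$type == "thiol_s") {
    if (state == "protonated") {
      g$atoms$charge[v] <- 0L; g$atoms$h[v] <- 1L
    } else {
      g$atoms$charge[v] <- -1L; g$atoms$h[v] <- 0L
    }
  } else if (site$type == "amine_n") {
    cur_q <- g$atoms$charge[v]
    if (state == "protonated" && cur_q == 0L) {
      g$atoms$charge[v] <- 1L; g$atoms$h[v] <- g$atoms$h[v] + 1L
    } else if (state == "neutral" && cur_q == 1L) {
      g$atoms$charge[v] <- 0L; g$atoms$h[v] <- g$atoms$h[v] - 1L
    } else if (state == "protonated" && cur_q == 1L) {
      # already protonated
    } else if (state == "neutral" && cur_q == 0L) {
      # already neutral
    }
  }
  g
}

#' Enumerate protonation states
#'
#' Identifies (de)protonatable sites with a packaged rule table
#' (carboxylic acid/carboxylate, non-amide amine/ammonium,
#' thiol/thiolate) and emits all combinations of site states, including
#' combinations that would not co-occur at any single pH. The seed is one
#' of the combinations.
#'
#' @param smiles canonical SMILES string.
#' @return character vector of canonical SMILES (seed included).
#' @export
enumerate_protonation_states <- function(smiles) {
  g <- parse_smiles(smiles)
  sites <- .protonation_sites(g)
  if (length(sites) == 0L) return(canonical_smiles(g))
  states_per_site <- lapply(sites, function(s) {
    if (s$type == "amine_n") c("neutral", "protonated")
    else c("protonated", "deprotonated")
  })
  combos <- expand.grid(states_per_site, stringsAsFactors = FALSE)
  out <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    gg <- g
    for (k in seq_along(sites))
      gg <- .apply_site_state(gg, sites[[k]], combos[r, k])
    out[r] <- canonical_smiles(gg)
  }
  sort(unique(out))
}

# --- stereoisomers -----------------------------------------------------------

.bond_in_ring <- function(g, i, j) {
  g2 <- g
  k <- which((g2$bonds$i == i & g2$bonds$j == j) |
               (g2$bonds$i == j & g2$bonds$j == i))
  g2$bonds <- g2$bonds[-k, , drop = FALSE]
  graph_connected(g2)
}

#' Enumerate stereoisomers
#'
#' Detects potential tetrahedral stereocentres (four substituents that are
#' pairwise inequivalent under the molecule's graph automorphisms) and
#' stereogenic non-ring double bonds, then emits all combinations of
#' winding orders and cis/trans orientations. Any stereo descriptors
#' already on the input are discarded first, so every output has fully
#' specified stereochemistry and the full combination set is returned.
#'
#' @param smiles SMILES string (stereo possibly unassigned or partial).
#' @return character vector of canonical SMILES, duplicates removed.
#' @export
enumerate_stereoisomers <- function(smiles) {
  g <- parse_smiles(smiles)
  g$stereo_atoms <- list()
  g$stereo_bonds <- list()
  nb <- neighbour_list(g)
  auts <- suppressWarnings(graph_automorphisms(g))
  el <- g$atoms$element

  fixes_nbrs <- function(v) {
    # TRUE iff no automorphism fixing v permutes v's neighbours
    for (sigma in auts) {
      if (sigma[v] != v) next
      if (any(sigma[nb[[v]]] != nb[[v]])) return(FALSE)
    }
    TRUE
  }

  centres <- integer(0)
  for (v in seq_len(nrow(g$atoms))) {
    nsub <- length(nb[[v]]) + g$atoms$h[v]
    if (nsub != 4L || g$atoms$h[v] > 1L) next
    if (any(vapply(nb[[v]], function(o)
      bond_order_of(g, v, o) != 1, logical(1)))) next
    if (!fixes_nbrs(v)) next
    centres <- c(centres, v)
  }

  dbonds <- list()
  for (k in which(g$bonds$order == 2)) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    if (.bond_in_ring(g, i, j)) next
    end_ok <- function(v, u) {
      subs <- setdiff(nb[[v]], u)
      nh <- g$atoms$h[v]
      if (length(subs) + nh != 2L) return(FALSE)  # sp2 with two substituents
      if (nh == 2L) return(FALSE)                 # =CH2 terminal
      if (any(vapply(subs, function(o)
        bond_order_of(g, v, o) != 1, logical(1)))) return(FALSE)
      if (length(subs) == 2L) {
        # two heavy substituents: must be inequivalent under automorphisms
        # that fix both double-bond ends
        for (sigma in auts) {
          if (sigma[v] != v || sigma[u] != u) next
          if (any(sigma[subs] != subs)) return(FALSE)
        }
      }
      TRUE
    }
    if (end_ok(i, j) && end_ok(j, i))
      dbonds[[length(dbonds) + 1L]] <- list(i = i, j = j)
  }

  if (length(centres) == 0L && length(dbonds) == 0L)
    return(canonical_smiles(g))

  nco <- length(centres); ndb <- length(dbonds)
  combos <- expand.grid(rep(list(c(-1L, 1L)), nco + ndb))
  out <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    gg <- g
    if (nco > 0L) {
      gg$stereo_atoms <- lapply(seq_len(nco), function(k) {
        v <- centres[k]
        nbrs <- nb[[v]]
        if (g$atoms$h[v] == 1L) nbrs <- c(0L, nbrs)
        list(atom = v, nbrs = nbrs, parity = combos[r, k])
      })
    }
    if (ndb > 0L) {
      gg$stereo_bonds <- lapply(seq_len(ndb), function(k) {
        db <- dbonds[[k]]
        ref_i <- setdiff(nb[[db$i]], db$j)[1L]
        ref_j <- setdiff(nb[[db$j]], db$i)[1L]
        list(i = db$i, j = db$j, ref_i = ref_i, ref_j = ref_j,
             same_side = combos[r, nco + k] == 1L)
      })
    }
    out[r] <- canonical_smiles(gg)
  }
  sort(unique(out))
}

# --- amons (subgraphs) -------------------------------------------------------

# enumerate all connected induced subgraphs with <= kmax vertices (ESU-style
# extension enumeration; each subgraph produced exactly once)
.connected_subsets <- function(nb, n, kmax) {
  res <- list()
  extend <- function(sub, ext, root) {
    res[[length(res) + 1L]] <<- sub
    if (length(sub) >= kmax) return()
    while (length(ext) > 0L) {
      w <- ext[1L]
      ext <- ext[-1L]
      new_ext <- c(ext, setdiff(nb[[w]][nb[[w]] > root],
                                c(sub, ext, unlist(nb[sub]))))
      extend(c(sub, w), new_ext, root)
    }
  }
  for (v in seq_len(n)) {
    extend(v, nb[[v]][nb[[v]] > v], v)
  }
  res
}

#' Generate amons (saturated connected subgraphs)
#'
#' Records each heavy atom's valency, enumerates all connected
#' heavy-atom-induced subgraphs (bonds between chosen atoms retained with
#' their orders), and saturates every fragment with hydrogens until each
#' heavy atom reaches the valency it had in the seed. Aromatic seeds are
#' kekulized first so fragment valencies are integral.
#'
#' @param smiles canonical SMILES of the seed.
#' @param max_heavy largest fragment size to enumerate (default 8); the
#'   seed itself is included when it fits.
#' @return character vector of canonical SMILES (deduplicated).
#' @export
generate_amons <- function(smiles, max_heavy = 8L) {
  g <- kekulize(parse_smiles(smiles))
  g$stereo_atoms <- list()
  g$stereo_bonds <- list()
  n <- nrow(g$atoms)
  nb <- neighbour_list(g)
  bsum <- .bond_order_sum(g)
  target_h <- g$atoms$h  # hydrogens present in the seed
  subsets <- .connected_subsets(nb, n, min(max_heavy, n))
  out <- character(0)
  for (sub in subsets) {
    sub <- sort(sub)
    gg <- delete_atoms(g, setdiff(seq_len(n), sub))
    inner_bsum <- .bond_order_sum(gg)
    # valency target: original bond-order sum + original H count
    gg$atoms$h <- as.integer(ceiling(bsum[sub]) + target_h[sub] -
                               ceiling(inner_bsum))
    if (any(gg$atoms$h < 0L)) next
    out <- c(out, canonical_smiles(gg))
  }
  sort(unique(out))
}

#' Filter by heavy-atom count
#'
#' @param smiles_set character vector of SMILES.
#' @param max_heavy maximum number of heavy atoms (default 8).
#' @return the subset with heavy-atom count at most `max_heavy`.
#' @export
filter_heavy_atoms <- function(smiles_set, max_heavy = 8L) {
  keep <- vapply(smiles_set, function(s) heavy_atom_count(s) <= max_heavy,
                 logical(1))
  smiles_set[keep]
}
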