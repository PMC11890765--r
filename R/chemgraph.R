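# Chemical-graph data model and the graph-level operations of the import
# pipeline: sanitisation, canonicalisation, electronic-state assignment and
# enantiomer-representative selection.
#
# Canonical atom ranks are obtained from igraph's BLISS canonical labelling
# on an auxiliary coloured graph in which every bond is subdivided by a
# vertex coloured with the bond order (BLISS itself only sees vertex
# colours). Stereo descriptors do not enter the colouring; instead, when a
# molecule carries stereo information, the writer is run over all graph
# automorphisms and the lexicographically smallest string is kept, so that
# e.g. meso forms collapse to a single representative.

#' @export
print.chemgraph <- function(x, ...) {
  cat("<chemgraph> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds, ",
      length(x$stereo_atoms), " stereo centres, ",
      length(x$stereo_bonds), " stereo bonds\n", sep = "")
  invisible(x)
}

#' Construct a chemical graph from parts
#'
#' Programmatic constructor used by graph enumeration and the peptide
#' builder. Implicit hydrogen counts are filled from the valency table
#' unless given explicitly.
#'
#' @param elements character vector of element symbols.
#' @param bonds data.frame with columns i, j, order (1, 1.5, 2 or 3).
#' @param charge integer vector of formal charges (default all zero).
#' @param h explicit per-atom hydrogen counts, or NULL to derive them.
#' @param valency valency table.
#' @return chemgraph.
#' @export
new_chemgraph <- function(elements, bonds, charge = NULL, h = NULL,
                          valency = default_valency()) {
  n <- length(elements)
  if (is.null(charge)) charge <- integer(n)
  if (nrow(bonds) > 0L) {
    stopifnot(all(bonds$i >= 1L), all(bonds$j >= 1L),
              all(bonds$i <= n), all(bonds$j <= n), all(bonds$i != bonds$j))
  }
  bsum <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    bsum[bonds$i[k]] <- bsum[bonds$i[k]] + bonds$order[k]
    bsum[bonds$j[k]] <- bsum[bonds$j[k]] + bonds$order[k]
  }
  adj <- adjusted_valency(elements, charge, valency)
  if (is.null(h)) {
    h <- adj - as.integer(ceiling(bsum))
    if (any(h < 0L))
      stop("bond orders exceed valency for atom(s) ",
           paste(which(h < 0L), collapse = ", "))
  }
  atoms <- data.frame(element = elements, charge = as.integer(charge),
                      h = as.integer(h), aromatic = rep(FALSE, n),
                      isotope = rep(NA_integer_, n), stringsAsFactors = FALSE)
  structure(list(atoms = atoms,
                 bonds = as.data.frame(bonds),
                 stereo_atoms = list(), stereo_bonds = list(),
                 valency = valency),
            class = "chemgraph")
}

#' Number of heavy (non-hydrogen) atoms
#' @param x chemgraph or SMILES string.
#' @return integer count.
#' @export
heavy_atom_count <- function(x) {
  g <- if (inherits(x, "chemgraph")) x else parse_smiles(x)
  sum(g$atoms$element != "H")
}

#' Sanitize a SMILES string
#'
#' Strips isotope labels and rejects disconnected ('.') or unparsable
#' input; the string is otherwise unchanged. Bracket atoms whose only
#' bracket-worthy feature was the isotope are un-bracketed (so `[13C]C`
#' becomes `CC`).
#'
#' @param smiles SMILES string.
#' @return sanitized SMILES string.
#' @export
sanitize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("SMILES must be a single string")
  if (grepl(".", smiles, fixed = TRUE))
    stop("disconnected SMILES (containing '.') are rejected: ", smiles)
  # drop brackets entirely when only an isotope + organic-subset symbol
  out <- gsub(sprintf("\\[[0-9]+(%s)\\]", paste(organic_subset(),
                                                collapse = "|")),
              "\\1", smiles)
  # otherwise just strip the isotope digits
  out <- gsub("\\[[0-9]+", "[", out)
  parse_smiles(out)  # errors propagate for unparsable input
  out
}

# canonical atom ranks via BLISS on the edge-subdivided coloured graph
canonical_ranks <- function(g) {
  na <- nrow(g$atoms)
  nb <- nrow(g$bonds)
  akey <- paste(g$atoms$element, g$atoms$charge, g$atoms$h, g$atoms$aromatic)
  acol <- as.integer(factor(akey, levels = sort(unique(akey))))
  if (na == 1L) return(1L)
  bcol <- max(acol) +
    as.integer(factor(g$bonds$order, levels = sort(unique(g$bonds$order))))
  ev <- rbind(cbind(g$bonds$i, na + seq_len(nb)),
              cbind(g$bonds$j, na + seq_len(nb)))
  ig <- igraph::add_edges(igraph::make_empty_graph(na + nb, directed = FALSE),
                          as.vector(t(ev)))
  lab <- igraph::canonical_permutation(ig, colors = c(acol, bcol))$labeling
  as.integer(rank(lab[seq_len(na)]))
}

# atom-level igraph with colour vectors, shared by automorphism search
.colored_igraph <- function(g) {
  na <- nrow(g$atoms)
  akey <- paste(g$atoms$element, g$atoms$charge, g$atoms$h, g$atoms$aromatic)
  acol <- as.integer(factor(akey, levels = sort(unique(akey))))
  ecol <- as.integer(factor(g$bonds$order,
                            levels = sort(unique(g$bonds$order))))
  ig <- igraph::make_empty_graph(na, directed = FALSE)
  if (nrow(g$bonds) > 0L)
    ig <- igraph::add_edges(ig, as.vector(t(cbind(g$bonds$i, g$bonds$j))))
  list(graph = ig, vcol = acol, ecol = ecol)
}

#' All graph automorphisms of a molecule
#'
#' Automorphisms of the heavy-plus-explicit-atom graph respecting element,
#' charge, hydrogen count and bond orders (stereo descriptors are ignored).
#' Enumerated exactly with VF2; used for symmetry-aware RMSD and stereo
#' canonicalisation.
#'
#' @param g chemgraph.
#' @param cap maximum number of automorphisms to return (identity-only
#'   fallback with a warning beyond the cap).
#' @return list of integer permutations (`sigma[v]` = image of atom v).
#' @export
graph_automorphisms <- function(g, cap = 2000L) {
  n <- nrow(g$atoms)
  if (n == 1L) return(list(1L))
  cg <- .colored_igraph(g)
  cnt <- igraph::count_isomorphisms(cg$graph, cg$graph,
                                    vertex.color1 = cg$vcol,
                                    vertex.color2 = cg$vcol,
                                    edge.color1 = cg$ecol,
                                    edge.color2 = cg$ecol)
  if (cnt > cap) {
    warning("automorphism group of size ", cnt, " exceeds cap ", cap,
            "; using identity only")
    return(list(seq_len(n)))
  }
  maps <- igraph::isomorphisms(cg$graph, cg$graph,
                               vertex.color1 = cg$vcol,
                               vertex.color2 = cg$vcol,
                               edge.color1 = cg$ecol,
                               edge.color2 = cg$ecol)
  lapply(maps, as.integer)
}

# relabel atoms: p[old] = new index
permute_graph <- function(g, p) {
  inv <- order(p)
  g2 <- g
  g2$atoms <- g$atoms[inv, , drop = FALSE]
  rownames(g2$atoms) <- NULL
  g2$bonds$i <- p[g$bonds$i]
  g2$bonds$j <- p[g$bonds$j]
  g2$stereo_atoms <- lapply(g$stereo_atoms, function(s) {
    s$atom <- p[s$atom]
    s$nbrs <- ifelse(s$nbrs == 0L, 0L, p[pmax(s$nbrs, 1L)])
    s
  })
  g2$stereo_bonds <- lapply(g$stereo_bonds, function(s) {
    s$i <- p[s$i]; s$j <- p[s$j]
    s$ref_i <- p[s$ref_i]; s$ref_j <- p[s$ref_j]
    s
  })
  g2
}

#' Canonical SMILES of a chemical graph
#' @param g chemgraph.
#' @return canonical SMILES string (unique within this package's canonical
#'   form).
#' @export
canonical_smiles <- function(g) {
  r <- canonical_ranks(g)
  if (length(g$stereo_atoms) == 0L && length(g$stereo_bonds) == 0L)
    return(write_smiles(g, r))
  auts <- suppressWarnings(graph_automorphisms(g))
  # r[sigma] is an equally valid canonical rank assignment for every
  # automorphism sigma of the stereo-less graph; stereo marks differ
  # between them, so take the lexicographic minimum.
  cands <- vapply(auts, function(sigma) write_smiles(g, r[sigma]),
                  character(1))
  min(cands)
}

#' Canonicalize a SMILES string
#'
#' Deterministic; two SMILES spellings of the same configurational isomer
#' map to the same string, and the map is idempotent.
#'
#' @param smiles SMILES string (sanitized).
#' @param valency valency table.
#' @return canonical SMILES string.
#' @export
canonicalize <- function(smiles, valency = default_valency()) {
  canonical_smiles(parse_smiles(smiles, valency))
}

#' Mirror image of a molecule
#'
#' Reflection inverts every tetrahedral parity and preserves cis/trans
#' descriptors.
#'
#' @param g chemgraph.
#' @return chemgraph of the enantiomer.
#' @export
mirror_graph <- function(g) {
  g$stereo_atoms <- lapply(g$stereo_atoms, function(s) {
    s$parity <- -s$parity
    s
  })
  g
}

#' Select the enantiomer representative
#'
#' Of an enantiomeric pair only the lexicographically smaller canonical
#' SMILES is processed further; the other member is skipped.
#'
#' @param smiles canonical SMILES string.
#' @return list with `smiles` (the representative) and `kept` (FALSE when
#'   the input is the larger member of a distinct pair).
#' @export
enantiomer_representative <- function(smiles) {
  g <- parse_smiles(smiles)
  cs <- canonical_smiles(g)
  cm <- canonical_smiles(mirror_graph(g))
  if (cs == cm) return(list(smiles = cs, kept = TRUE))
  if (cs < cm) list(smiles = cs, kept = TRUE)
  else list(smiles = cm, kept = FALSE)
}

#' Electronic state of a molecule
#'
#' The total charge is the sum of all formal charges; the multiplicity is
#' the lowest consistent with the electron count (singlet for an even
#' number of electrons, doublet for odd).
#'
#' @param g chemgraph (or SMILES string).
#' @return list with `charge` and `multiplicity`.
#' @export
assign_electronic_state <- function(g) {
  if (!inherits(g, "chemgraph")) g <- parse_smiles(g)
  z <- sum(element_number(g$atoms$element)) + sum(g$atoms$h)
  q <- sum(g$atoms$charge)
  electrons <- z - q
  list(charge = q, multiplicity = if (electrons %% 2L == 0L) 1L else 2L)
}

#' Kekulize aromatic bonds
#'
#' Replaces aromatic (order 1.5) bonds by an alternating single/double
#' assignment found by backtracking over the valency deficits of the
#' aromatic atoms. Fails for aromatic systems without a Kekule structure.
#'
#' @param g chemgraph.
#' @return chemgraph with integer bond orders only.
#' @export
kekulize <- function(g) {
  arom_bonds <- which(g$bonds$order == 1.5)
  if (length(arom_bonds) == 0L) return(g)
  n <- nrow(g$atoms)
  bsum1 <- numeric(n)  # order sum with aromatic bonds counted as single
  for (k in seq_len(nrow(g$bonds))) {
    o <- if (g$bonds$order[k] == 1.5) 1 else g$bonds$order[k]
    bsum1[g$bonds$i[k]] <- bsum1[g$bonds$i[k]] + o
    bsum1[g$bonds$j[k]] <- bsum1[g$bonds$j[k]] + o
  }
  adj <- adjusted_valency(g$atoms$element, g$atoms$charge, g$valency)
  need <- adj - (bsum1 + g$atoms$h)
  if (any(need < 0 | need > 1))
    stop("cannot kekulize: irregular valency deficit")
  need <- as.logical(need)
  # perfect matching of deficit atoms over aromatic edges, by backtracking
  ei <- g$bonds$i[arom_bonds]; ej <- g$bonds$j[arom_bonds]
  assigned <- logical(length(arom_bonds))
  matched <- !need
  solve <- function() {
    v <- which(!matched)[1L]
    if (is.na(v)) return(TRUE)
    for (k in seq_along(arom_bonds)) {
      if (assigned[k]) next
      u <- if (ei[k] == v) ej[k] else if (ej[k] == v) ei[k] else next
      if (matched[u]) next
      assigned[k] <<- TRUE; matched[v] <<- TRUE; matched[u] <<- TRUE
      if (solve()) return(TRUE)
      assigned[k] <<- FALSE; matched[v] <<- FALSE; matched[u] <<- FALSE
    }
    FALSE
  }
  if (!solve()) stop("cannot kekulize: no perfect matching")
  g$bonds$order[arom_bonds] <- ifelse(assigned, 2, 1)
  g$atoms$aromatic <- FALSE
  g
}

#' Read a SMILES line file
#'
#' One record per line; blank lines and lines beginning with '#' are
#' ignored; anything after whitespace on a line is treated as a comment.
#'
#' @param path file path.
#' @return character vector of SMILES strings.
#' @export
read_smiles_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "[[:space:]]+"), `[[`, character(1), 1L)
}

#' Write a SMILES line file
#' @param smiles character vector.
#' @param path file path.
#' @param header optional comment lines written with a '#' prefix.
#' @export
write_smiles_file <- function(smiles, path, header = NULL) {
  out <- character(0)
  if (!is.null(header)) out <- paste0("# ", header)
  writeLines(c(out, smiles), path)
  invisible(path)
}
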