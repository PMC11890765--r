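# Tripeptide generation from the 22 proteinogenic amino acids (including
# selenocysteine and pyrrolysine): all 22^3 ordered triples as linear
# tripeptides; for triples with at least two cysteines, disulfide-bridged
# variants (every cysteine pairing; all pairings for tricysteine); and
# split variants obtained by hydrolysing peptide bonds of the bridged
# forms, keeping only products that remain covalently connected through
# the bridge. Counts are reported for the generated multiset - canonical
# deduplication happens downstream at import, as for every other source.

# L-amino-acid SMILES written with a fixed convention: the backbone
# nitrogen is the first atom and the backbone carboxyl group C(=O)O forms
# the last three atoms, so condensation sites are known by position.
.amino_acids <- c(
  Ala = "N[C@@H](C)C(=O)O",
  Arg = "N[C@@H](CCCNC(=N)N)C(=O)O",
  Asn = "N[C@@H](CC(=O)N)C(=O)O",
  Asp = "N[C@@H](CC(=O)O)C(=O)O",
  Cys = "N[C@@H](CS)C(=O)O",
  Gln = "N[C@@H](CCC(=O)N)C(=O)O",
  Glu = "N[C@@H](CCC(=O)O)C(=O)O",
  Gly = "NCC(=O)O",
  His = "N[C@@H](CC1=CNC=N1)C(=O)O",
  Ile = "N[C@@H]([C@@H](C)CC)C(=O)O",
  Leu = "N[C@@H](CC(C)C)C(=O)O",
  Lys = "N[C@@H](CCCCN)C(=O)O",
  Met = "N[C@@H](CCSC)C(=O)O",
  Phe = "N[C@@H](CC1=CC=CC=C1)C(=O)O",
  Pro = "N1CCC[C@H]1C(=O)O",
  Ser = "N[C@@H](CO)C(=O)O",
  Thr = "N[C@@H]([C@H](C)O)C(=O)O",
  Trp = "N[C@@H](CC1=CNC2=CC=CC=C21)C(=O)O",
  Tyr = "N[C@@H](CC1=CC=C(O)C=C1)C(=O)O",
  Val = "N[C@@H](C(C)C)C(=O)O",
  Sec = "N[C@@H](C[SeH])C(=O)O",
  Pyl = "N[C@@H](CCCCNC(=O)[C@@H]1N=CC[C@H]1C)C(=O)O"
)

#' The packaged amino-acid table
#'
#' @return data.frame with columns `code` and `smiles` for the 22
#'   proteinogenic amino acids.
#' @export
amino_acid_table <- function() {
  data.frame(code = names(.amino_acids), smiles = unname(.amino_acids),
             stringsAsFactors = FALSE)
}

# parse one amino acid and locate its condensation sites
.aa_residue <- function(code) {
  smi <- .amino_acids[[code]]
  if (is.null(smi)) stop("unknown amino acid code: ", code)
  g <- parse_smiles(smi)
  n <- nrow(g$atoms)
  stopifnot(g$atoms$element[1L] == "N",
            identical(g$atoms$element[(n - 2L):n], c("C", "O", "O")))
  thiol <- if (code == "Cys") {
    which(g$atoms$element == "S" & g$atoms$h == 1L)
  } else integer(0)
  list(graph = g, n_idx = 1L, c_idx = n - 2L, oh_idx = n, thiol = thiol)
}

# concatenate residue graphs and form the peptide bonds
.assemble_peptide <- function(residues) {
  atoms <- NULL; bonds <- NULL
  stereo_atoms <- list(); stereo_bonds <- list()
  offset <- 0L
  offs <- integer(length(residues))
  for (k in seq_along(residues)) {
    g <- residues[[k]]$graph
    offs[k] <- offset
    atoms <- rbind(atoms, g$atoms)
    b <- g$bonds
    b$i <- b$i + offset
    b$j <- b$j + offset
    bonds <- rbind(bonds, b)
    for (s in g$stereo_atoms) {
      s$atom <- s$atom + offset
      s$nbrs <- ifelse(s$nbrs == 0L, 0L, s$nbrs + offset)
      stereo_atoms[[length(stereo_atoms) + 1L]] <- s
    }
    for (s in g$stereo_bonds) {
      s$i <- s$i + offset; s$j <- s$j + offset
      s$ref_i <- s$ref_i + offset; s$ref_j <- s$ref_j + offset
      stereo_bonds[[length(stereo_bonds) + 1L]] <- s
    }
    offset <- offset + nrow(g$atoms)
  }
  g <- structure(list(atoms = atoms, bonds = bonds,
                      stereo_atoms = stereo_atoms,
                      stereo_bonds = stereo_bonds,
                      valency = residues[[1L]]$graph$valency),
                 class = "chemgraph")
  rownames(g$atoms) <- NULL
  rownames(g$bonds) <- NULL

  # condense: drop the carboxyl OH of residue k, bond its C to the next
  # backbone N (which loses one hydrogen)
  drop <- integer(0)
  peptide_bonds <- list()
  for (k in seq_len(length(residues) - 1L)) {
    c_at <- residues[[k]]$c_idx + offs[k]
    oh_at <- residues[[k]]$oh_idx + offs[k]
    n_at <- residues[[k + 1L]]$n_idx + offs[k + 1L]
    drop <- c(drop, oh_at)
    g$bonds <- rbind(g$bonds, data.frame(i = c_at, j = n_at, order = 1))
    g$atoms$h[n_at] <- g$atoms$h[n_at] - 1L
    peptide_bonds[[k]] <- c(c_at, n_at)
  }
  thiols <- unlist(lapply(seq_along(residues), function(k)
    residues[[k]]$thiol + offs[k]))

  # delete dropped OH atoms, remapping the tracked indices
  keep <- setdiff(seq_len(nrow(g$atoms)), drop)
  remap <- integer(nrow(g$atoms))
  remap[keep] <- seq_along(keep)
  g <- delete_atoms(g, drop)
  peptide_bonds <- lapply(peptide_bonds, function(pb) remap[pb])
  thiols <- remap[thiols]
  list(graph = g, peptide_bonds = peptide_bonds, thiols = thiols)
}

.add_disulfide <- function(pep, s1, s2) {
  g <- pep$graph
  stopifnot(g$atoms$h[s1] >= 1L, g$atoms$h[s2] >= 1L)
  g$atoms$h[c(s1, s2)] <- g$atoms$h[c(s1, s2)] - 1L
  g$bonds <- rbind(g$bonds, data.frame(i = s1, j = s2, order = 1))
  pep$graph <- g
  pep
}

# hydrolyse the given peptide bonds: remove C-N, restore N-H and add an OH
.split_peptide_bonds <- function(pep, which_bonds) {
  g <- pep$graph
  for (w in which_bonds) {
    pb <- pep$peptide_bonds[[w]]
    k <- which((g$bonds$i == pb[1L] & g$bonds$j == pb[2L]) |
                 (g$bonds$i == pb[2L] & g$bonds$j == pb[1L]))
    g$bonds <- g$bonds[-k, , drop = FALSE]
    g$atoms$h[pb[2L]] <- g$atoms$h[pb[2L]] + 1L
    g$atoms <- rbind(g$atoms, data.frame(element = "O", charge = 0L, h = 1L,
                                         aromatic = FALSE,
                                         isotope = NA_integer_))
    g$bonds <- rbind(g$bonds,
                     data.frame(i = pb[1L], j = nrow(g$atoms), order = 1))
  }
  rownames(g$atoms) <- NULL
  pep$graph <- g
  pep
}

#' Assemble one linear peptide as a chemical graph
#'
#' @param codes character vector of amino-acid codes (N- to C-terminus).
#' @return list with `graph`, `peptide_bonds` (atom-index pairs) and
#'   `thiols` (cysteine sulfur indices).
#' @export
assemble_peptide <- function(codes) {
  .assemble_peptide(lapply(codes, .aa_residue))
}

#' Generate all tripeptides and their disulfide/split variants
#'
#' Linear peptides are emitted by fragment concatenation (the table's
#' fixed writing convention makes the condensation a string operation,
#' cross-checked against the graph assembler in the test suite); bridged
#' and split variants are built at the graph level so the
#' covalent-connectivity rule is checked on the actual molecule.
#'
#' @param canonical canonicalize the emitted SMILES (slower; counts are
#'   unaffected). With `canonical = FALSE` plain SMILES are returned.
#' @param codes amino-acid codes to combine (default: all 22).
#' @return list with `smiles` (character multiset of all generated
#'   structures) and the count report `n_linear`, `n_bridged`, `n_split`,
#'   `n_total`.
#' @export
generate_tripeptides <- function(canonical = FALSE,
                                 codes = names(.amino_acids)) {
  smis <- .amino_acids[codes]
  if (anyNA(names(smis))) stop("unknown amino acid code(s)")
  stopifnot(all(endsWith(smis, "C(=O)O")))
  frag <- sub("O$", "", smis)  # drop the hydroxyl; next N condenses onto C

  triples <- expand.grid(c = codes, b = codes, a = codes,
                         stringsAsFactors = FALSE)[, 3:1]
  linear <- paste0(frag[triples$a], frag[triples$b], smis[triples$c])
  n_linear <- length(linear)

  # bridged + split variants: triples with at least two cysteines
  residues <- lapply(codes, .aa_residue)
  names(residues) <- codes
  n_bridged <- 0L; n_split <- 0L
  variants <- character(0)
  ncys <- (triples$a == "Cys") + (triples$b == "Cys") + (triples$c == "Cys")
  for (r in which(ncys >= 2L)) {
    pep <- .assemble_peptide(residues[c(triples$a[r], triples$b[r],
                                        triples$c[r])])
    ths <- pep$thiols
    pairs <- utils::combn(length(ths), 2L)
    for (pc in seq_len(ncol(pairs))) {
      bridged <- .add_disulfide(pep, ths[pairs[1L, pc]], ths[pairs[2L, pc]])
      n_bridged <- n_bridged + 1L
      variants <- c(variants, write_smiles(bridged$graph))
      nb <- length(bridged$peptide_bonds)
      for (mask in seq_len(2^nb - 1L)) {
        sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nb) - 1L)) != 0L)
        cand <- .split_peptide_bonds(bridged, sel)
        if (graph_connected(cand$graph)) {
          n_split <- n_split + 1L
          variants <- c(variants, write_smiles(cand$graph))
        }
      }
    }
  }
  smiles <- c(linear, variants)
  if (canonical) smiles <- vapply(smiles, canonicalize, character(1),
                                  USE.NAMES = FALSE)
  list(smiles = smiles,
       n_linear = n_linear, n_bridged = n_bridged, n_split = n_split,
       n_total = n_linear + n_bridged + n_split)
}
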