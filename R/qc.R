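# Automated consistency checks and outlier flagging: graph/bond-order
# consistency (hard filter for conformers), the four outlier criteria
# (positive formation energy, extreme per-atom force, short normalised
# contact, dissociated bond), and NPR shape descriptors.

#' Bond-order consistency with the parent graph
#'
#' TRUE iff no bonded pair's computed bond order deviates from the order
#' expected from graph connectivity (1, 1.5, 2, 3 for single, aromatic,
#' double, triple) by more than `tol`.
#'
#' @param g chemgraph (parent graph; hydrogens implicit).
#' @param BO N x N bond-order matrix over the explicit atoms (heavy atoms
#'   in graph order, then hydrogens as from [explicit_atoms()]).
#' @param tol maximum allowed deviation (default 0.5).
#' @return logical.
#' @export
bond_order_consistency <- function(g, BO, tol = forge_constants$bo_tol) {
  ex <- explicit_atoms(g, kekulize = FALSE)
  if (nrow(BO) != length(ex$elements) || !isTRUE(all.equal(BO, t(BO))))
    stop("bond-order matrix does not match the explicit atom count")
  for (k in seq_len(nrow(ex$bonds))) {
    i <- ex$bonds$i[k]; j <- ex$bonds$j[k]
    if (abs(BO[i, j] - ex$bonds$order[k]) > tol) return(FALSE)
  }
  TRUE
}

#' Formation energy
#'
#' Total energy minus the summed isolated-atom reference energies of the
#' composition; positive values indicate instability against atomization.
#'
#' @param E_total total energy (eV).
#' @param composition character vector of element symbols (one per atom).
#' @param ref named numeric vector of isolated-atom reference energies.
#' @return formation energy (eV).
#' @export
formation_energy <- function(E_total, composition, ref) {
  miss <- setdiff(unique(composition), names(ref))
  if (length(miss) > 0L)
    stop("reference energies missing for: ", paste(miss, collapse = ", "))
  E_total - sum(ref[composition])
}

#' Isolated-atom reference energies for the toy calculator
#'
#' Computed by evaluating the toy force field on single-atom systems (a
#' lone atom has no interaction terms).
#'
#' @param elements element symbols to cover.
#' @return named numeric vector (eV).
#' @export
toy_reference_energies <- function(elements) {
  vapply(unique(elements), function(el) {
    g <- new_chemgraph(el, data.frame(i = integer(), j = integer(),
                                      order = numeric()))
    g$atoms$h <- 0L  # a bare atom, not the hydride
    ff <- toy_forcefield(g)
    s <- structure3d(element_number(el), matrix(0, 1L, 3L))
    evaluate_calculator(ff, s, "energy")$energy
  }, numeric(1))
}

#' Minimum normalised inter-atomic distance
#'
#' min over pairs of r_ij / (R_i + R_j); a value of 1 roughly corresponds
#' to a typical equilibrium bond length.
#'
#' @param s structure3d.
#' @param radii optional named radii table (Angstrom); covalent radii by
#'   default.
#' @return the minimum ratio; +Inf for single atoms.
#' @export
normalized_min_distance <- function(s, radii = NULL) {
  n <- length(s$numbers)
  if (n < 2L) return(Inf)
  el <- element_symbol(s$numbers)
  R <- if (is.null(radii)) covalent_radius(el) else unname(radii[el])
  d <- as.matrix(stats::dist(s$positions))
  ratio <- d / outer(R, R, `+`)
  min(ratio[upper.tri(ratio)])
}

#' Default outlier thresholds
#' @return named list (internal eV / Angstrom units).
#' @export
outlier_thresholds <- function() {
  list(formation_energy = 0,
       max_force = forge_constants$f_max_outlier,   # 0.5 Hartree/Bohr
       min_norm_distance = forge_constants$d_norm_min,
       bond_order = forge_constants$bo_dissoc)
}

#' Evaluate the four outlier criteria
#'
#' @param record list with `energy` (eV), `forces` (N x 3, eV/A),
#'   `bond_orders` (N x N) and `formation_energy` (eV).
#' @param g parent chemgraph (bonded pairs for the dissociation check are
#'   taken from it, hydrogens included).
#' @param s structure3d of the record's geometry.
#' @param thresholds see [outlier_thresholds()].
#' @param force_norm "norm" (Euclidean per-atom force norm, default) or
#'   "component" (maximum absolute component).
#' @return list of flags: `positive_formation_energy`,
#'   `max_force_exceeded`, `min_norm_distance_low`, `bond_dissociated`,
#'   `is_outlier` (OR of the four).
#' @export
flag_outlier <- function(record, g, s, thresholds = outlier_thresholds(),
                         force_norm = c("norm", "component")) {
  force_norm <- match.arg(force_norm)
  req <- c("forces", "bond_orders", "formation_energy")
  miss <- req[!req %in% names(record)]
  if (length(miss) > 0L)
    stop("record is missing fields: ", paste(miss, collapse = ", "))
  fmag <- if (force_norm == "norm") {
    sqrt(rowSums(record$forces^2))
  } else {
    apply(abs(record$forces), 1L, max)
  }
  ex <- explicit_atoms(g, kekulize = FALSE)
  dissoc <- FALSE
  for (k in seq_len(nrow(ex$bonds))) {
    if (record$bond_orders[ex$bonds$i[k], ex$bonds$j[k]] <
        thresholds$bond_order) {
      dissoc <- TRUE
      break
    }
  }
  flags <- list(
    positive_formation_energy =
      record$formation_energy > thresholds$formation_energy,
    max_force_exceeded = max(fmag) > thresholds$max_force,
    min_norm_distance_low =
      normalized_min_distance(s) < thresholds$min_norm_distance,
    bond_dissociated = dissoc)
  flags$is_outlier <- flags$positive_formation_energy ||
    flags$max_force_exceeded || flags$min_norm_distance_low ||
    flags$bond_dissociated
  flags
}

#' Normalised principal-moment-of-inertia ratios (NPR)
#'
#' Shape descriptors (I1/I3, I2/I3) from the mass-weighted inertia
#' tensor: rod (0, 1), disc (0.5, 0.5), sphere (1, 1).
#'
#' @param s structure3d.
#' @param masses atomic masses; element masses by default.
#' @return named numeric vector c(npr1, npr2).
#' @export
npr <- function(s, masses = NULL) {
  n <- length(s$numbers)
  if (n < 2L) stop("NPR requires at least two atoms")
  if (is.null(masses)) masses <- element_mass(element_symbol(s$numbers))
  mom <- .inertia_moments(masses, s$positions)
  if (mom[3L] <= 0) stop("all atoms coincident")
  c(npr1 = mom[1L] / mom[3L], npr2 = mom[2L] / mom[3L])
}
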