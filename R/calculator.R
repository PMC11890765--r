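# Pluggable potential-energy calculator contract.
#
# A calculator is any object with class c("<name>", "forge_calculator")
# implementing evaluate_calculator() for the capabilities it declares.
# Internal units are Angstrom / eV everywhere; conversions to the export
# units (Hartree, Bohr) happen only in the records module.

#' Construct a 3D structure
#'
#' @param numbers atomic numbers (length N).
#' @param positions N x 3 matrix of Cartesian coordinates, Angstrom.
#' @param charge total charge (e).
#' @param multiplicity spin multiplicity.
#' @param graph_key,conformer_key optional parent keys.
#' @return `structure3d` object.
#' @export
structure3d <- function(numbers, positions, charge = 0L, multiplicity = 1L,
                        graph_key = NULL, conformer_key = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  numbers <- as.integer(numbers)
  stopifnot(length(numbers) >= 1L, nrow(positions) == length(numbers),
            all(is.finite(positions)), all(numbers >= 1L),
            multiplicity >= 1L)
  structure(list(numbers = numbers, positions = positions,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 graph_key = graph_key, conformer_key = conformer_key),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", length(x$numbers), " atoms, charge ", x$charge,
      ", multiplicity ", x$multiplicity, "\n", sep = "")
  invisible(x)
}

#' Capabilities of a calculator
#' @param calc calculator object.
#' @return character vector, subset of energy, forces, bond_orders,
#'   partial_charges.
#' @export
calculator_capabilities <- function(calc) {
  UseMethod("calculator_capabilities")
}

#' Evaluate a calculator on a structure
#'
#' @param calc calculator object.
#' @param s `structure3d`.
#' @param properties requested properties (must be within the
#'   calculator's capabilities).
#' @return list with the requested entries: `energy` (eV), `forces`
#'   (N x 3, eV/A), `bond_orders` (N x N), `charges` (N).
#' @export
evaluate_calculator <- function(calc, s,
                                properties = c("energy", "forces")) {
  missing_caps <- setdiff(properties, calculator_capabilities(calc))
  if (length(missing_caps) > 0L)
    stop("calculator lacks capabilities: ",
         paste(missing_caps, collapse = ", "))
  UseMethod("evaluate_calculator")
}

#' Analytic Hessian of a calculator
#'
#' Available for the analytic calculators packaged here (toy force field,
#' harmonic); serves as the oracle for the finite-difference Hessian.
#'
#' @param calc calculator object.
#' @param s `structure3d`.
#' @return 3N x 3N symmetric matrix (eV/A^2), coordinate order
#'   (x1, y1, z1, x2, ...).
#' @export
analytic_hessian <- function(calc, s) {
  UseMethod("analytic_hessian")
}

# ---------------------------------------------------------------------------
# exactly quadratic calculator: E(x) = E0 + 1/2 (x-x0)' H (x-x0)

#' Exactly harmonic calculator
#'
#' A quadratic potential-energy surface around a reference geometry; the
#' instrument for round-trip tests of normal-mode sampling (on a quadratic
#' PES the realized energy equals the drawn energy exactly).
#'
#' @param x0 reference positions (N x 3).
#' @param H 3N x 3N symmetric positive semi-definite matrix (eV/A^2).
#' @param E0 energy at the reference.
#' @return calculator object.
#' @export
harmonic_calculator <- function(x0, H, E0 = 0) {
  x0 <- matrix(as.numeric(x0), ncol = 3L)
  stopifnot(nrow(H) == 3L * nrow(x0), isTRUE(all.equal(H, t(H))))
  structure(list(x0 = x0, H = H, E0 = E0),
            class = c("harmonic_calculator", "forge_calculator"))
}

#' @export
calculator_capabilities.harmonic_calculator <- function(calc) {
  c("energy", "forces")
}

#' @export
evaluate_calculator.harmonic_calculator <- function(calc, s,
    properties = c("energy", "forces")) {
  dx <- as.vector(t(s$positions - calc$x0))
  g <- calc$H %*% dx
  out <- list()
  if ("energy" %in% properties)
    out$energy <- calc$E0 + 0.5 * sum(dx * g)
  if ("forces" %in% properties)
    out$forces <- matrix(-g, ncol = 3L, byrow = TRUE)
  out
}

#' @export
analytic_hessian.harmonic_calculator <- function(calc, s) {
  calc$H
}

# ---------------------------------------------------------------------------

#' Check force-energy consistency of a calculator
#'
#' Central-difference gradient check: forces must equal -dE/dx within
#' `tol` for every coordinate.
#'
#' @param calc calculator.
#' @param s structure3d.
#' @param h step (Angstrom).
#' @param tol maximum absolute deviation (eV/A).
#' @return max absolute deviation (invisibly); errors are left to the
#'   caller's expectations.
#' @export
check_force_consistency <- function(calc, s, h = 1e-5, tol = 1e-4) {
  f <- evaluate_calculator(calc, s, c("energy", "forces"))$forces
  n <- length(s$numbers)
  dev <- 0
  for (a in seq_len(n)) for (k in 1:3) {
    sp <- s; sp$positions[a, k] <- sp$positions[a, k] + h
    sm <- s; sm$positions[a, k] <- sm$positions[a, k] - h
    ep <- evaluate_calculator(calc, sp, "energy")$energy
    em <- evaluate_calculator(calc, sm, "energy")$energy
    dev <- max(dev, abs(-(ep - em) / (2 * h) - f[a, k]))
  }
  invisible(dev)
}
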