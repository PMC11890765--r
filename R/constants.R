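#' Physical constants and unit conversions
#'
#' Canonical internal units are Angstrom (lengths) and eV (energies).
#' All externally stated thresholds are converted once, here, so the rest of
#' the package never mixes unit systems. On export, records use Hartree and
#' Bohr (see [export_jsonl()]).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{k_B}{Boltzmann constant, eV/K}
#'   \item{hartree_eV}{1 Hartree in eV}
#'   \item{bohr_A}{1 Bohr in Angstrom}
#'   \item{Jmol_eV}{1 J/mol in eV}
#'   \item{f_max_opt}{geometry-optimisation force threshold, eV/A (5 meV/A)}
#'   \item{e_tol_preopt}{pre-optimisation energy-change threshold, eV/atom
#'     (1 J mol^-1 atom^-1)}
#'   \item{f_max_outlier}{outlier force threshold, eV/A (0.5 Hartree/Bohr)}
#'   \item{d_norm_min}{outlier normalised-distance threshold (dimensionless)}
#'   \item{bo_dissoc}{outlier bond-order dissociation threshold}
#'   \item{bo_tol}{bond-order graph-consistency tolerance}
#'   \item{rmsd_dup}{conformer duplicate RMSD threshold, Angstrom}
#' }
#' @export
forge_constants <- local({
  hartree_eV <- 27.211386245988
  bohr_A <- 0.529177210903
  list(
    k_B = 8.617333262e-5,
    hartree_eV = hartree_eV,
    bohr_A = bohr_A,
    Jmol_eV = 1 / 96485.33212331001,
    f_max_opt = 5e-3,
    e_tol_preopt = 1 / 96485.33212331001,
    f_max_outlier = 0.5 * hartree_eV / bohr_A,
    d_norm_min = 0.5,
    bo_dissoc = 0.25,
    bo_tol = 0.5,
    rmsd_dup = 0.05
  )
})
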