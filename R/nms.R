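# Normal-mode analysis and off-equilibrium sampling.
#
# The Hessian is computed by finite differences of the forces with a
# six-point central stencil (offsets +-h, +-2h, +-3h; coefficients
# -+1, +-9, -+45 over 60h) at displacement h = 1e-3 A. Force constants
# k_i are eigenvalues of the mass-weighted Hessian and displacements
# delta_i are mass-weighted, so Cartesian displacement is
# M^(-1/2) * sum(delta_i q_i) and the harmonic energy identity
# E_i = k_i delta_i^2 / 2 is exact on a quadratic surface.

#' Finite-difference Hessian with stencil energies
#'
#' @param s structure3d at an optimized geometry.
#' @param calc calculator (energy + forces).
#' @param h displacement, Angstrom (default 1e-3).
#' @return list with `H` (3N x 3N, symmetrized), `stencil_energies`
#'   (3N x 6 matrix of the energies at every stencil point) and `E0`.
#' @export
finite_difference_hessian <- function(s, calc, h = 1e-3) {
  n3 <- 3L * length(s$numbers)
  offsets <- c(-3, -2, -1, 1, 2, 3) * h
  coef <- c(-1, 9, -45, 45, -9, 1) / (60 * h)
  H <- matrix(0, n3, n3)
  se <- matrix(NA_real_, n3, 6L)
  E0 <- evaluate_calculator(calc, s, "energy")$energy
  for (k in seq_len(n3)) {
    a <- (k - 1L) %/% 3L + 1L
    c3 <- (k - 1L) %% 3L + 1L
    dF <- numeric(n3)
    for (m in seq_along(offsets)) {
      sp <- s
      sp$positions[a, c3] <- sp$positions[a, c3] + offsets[m]
      r <- evaluate_calculator(calc, sp, c("energy", "forces"))
      if (!is.finite(r$energy)) stop("calculator failure at stencil point")
      se[k, m] <- r$energy
      dF <- dF + coef[m] * as.vector(t(r$forces))
    }
    H[, k] <- -dF   # H = -dF/dx
  }
  list(H = (H + t(H)) / 2, stencil_energies = se, E0 = E0)
}

#' Saddle-point check from stencil energies
#'
#' TRUE iff the energy increases at every displacement used for the
#' stencil; conformers failing this are not minima and are discarded.
#'
#' @param stencil_energies matrix from [finite_difference_hessian()].
#' @param E0 energy at the undisplaced geometry.
#' @return logical.
#' @export
saddle_point_check <- function(stencil_energies, E0) {
  all(stencil_energies > E0)
}

.inertia_moments <- function(masses, x) {
  com <- colSums(x * masses) / sum(masses)
  xc <- sweep(x, 2L, com)
  I <- matrix(0, 3L, 3L)
  for (a in seq_along(masses)) {
    r <- xc[a, ]
    I <- I + masses[a] * (sum(r^2) * diag(3L) - outer(r, r))
  }
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' Detect linearity from the principal moments of inertia
#' @param masses atomic masses (amu).
#' @param x N x 3 coordinates.
#' @param tol smallest-moment threshold (amu A^2).
#' @return logical.
#' @export
is_linear_structure <- function(masses, x, tol = 1e-3) {
  length(masses) <= 2L || .inertia_moments(masses, x)[1L] < tol
}

#' Normal-mode analysis
#'
#' Diagonalizes the mass-weighted Hessian, discards the six (five for
#' linear structures) rigid translation/rotation modes of smallest
#' absolute eigenvalue, and requires all remaining force constants to be
#' positive.
#'
#' @param H 3N x 3N Cartesian Hessian (eV/A^2).
#' @param masses atomic masses (amu).
#' @param s structure3d of the equilibrium geometry.
#' @return object of class `normal_modes`: list with `modes` (3N x n_f,
#'   mass-weighted orthonormal columns), `k` (force constants,
#'   eV/(A^2 amu)), `n_f`, `linear`, `masses`, `equilibrium`.
#' @export
normal_mode_analysis <- function(H, masses, s) {
  n <- length(masses)
  stopifnot(nrow(H) == 3L * n)
  linear <- is_linear_structure(masses, s$positions)
  n_rigid <- if (linear) 5L else 6L
  n_f <- 3L * n - n_rigid
  if (n_f < 1L) stop("no internal degrees of freedom")
  ms <- rep(masses, each = 3L)
  Hmw <- H / sqrt(outer(ms, ms))
  eg <- eigen(Hmw, symmetric = TRUE)
  keep <- order(abs(eg$values))[-seq_len(n_rigid)]
  keep <- keep[order(eg$values[keep])]
  k <- eg$values[keep]
  if (any(k <= 0))
    stop("negative internal force constant: not a minimum")
  structure(list(modes = eg$vectors[, keep, drop = FALSE], k = k,
                 n_f = n_f, linear = linear, masses = masses,
                 equilibrium = s),
            class = "normal_modes")
}

#' Draw a sample temperature and total energy
#'
#' T ~ Uniform(0, T_max); E = n_f k_B T / 2 (equipartition over the
#' internal degrees of freedom). Uses the R random number generator.
#'
#' @param n_f number of internal degrees of freedom.
#' @param T_max maximum temperature, K (default 1000).
#' @return list with `T` (K) and `E` (eV).
#' @export
draw_sample_energy <- function(n_f, T_max = 1000) {
  stopifnot(n_f >= 1L)
  Tk <- stats::runif(1L, 0, T_max)
  list(T = Tk, E = 0.5 * n_f * forge_constants$k_B * Tk)
}

#' Partition an energy over modes
#'
#' E_i = w_i^2 / sum(w^2) * E with standard-normal raw weights; the sum
#' of the parts equals E exactly by construction.
#'
#' @param E total energy (eV), non-negative.
#' @param n_f number of modes.
#' @return list with `w` (raw weights) and `E_vec`.
#' @export
partition_energy <- function(E, n_f) {
  stopifnot(E >= 0)
  repeat {
    w <- stats::rnorm(n_f)
    if (sum(w^2) > 0) break
  }
  E_vec <- w^2 / sum(w^2) * E
  # absorb the floating-point residual into the largest share so the sum
  # is exactly E
  res <- E - sum(E_vec)
  m <- which.max(E_vec)
  E_vec[m] <- E_vec[m] + res
  if (sum(E_vec) != E) E_vec[m] <- E_vec[m] + (E - sum(E_vec))
  list(w = w, E_vec = E_vec)
}

#' Mode displacements from mode energies
#'
#' delta_i = sign(w_i) sqrt(2 E_i / k_i), in the mass-weighted
#' coordinates matching the force-constant convention.
#'
#' @param E_vec mode energies (eV).
#' @param k_vec force constants (> 0).
#' @param w raw weights (sign carriers).
#' @return numeric vector of signed displacements.
#' @export
mode_displacements <- function(E_vec, k_vec, w) {
  if (any(k_vec <= 0)) stop("non-positive force constant")
  sign(w) * sqrt(2 * E_vec / k_vec)
}

#' Apply mode displacements to the equilibrium geometry
#'
#' Cartesian mode: x = x_eq + M^(-1/2) sum(delta_i q_i). Z-matrix mode:
#' each mode is transformed to internal-coordinate increments by a
#' two-sided finite difference along the mode, the increments are scaled
#' by delta_i and summed (dihedrals wrapped to the minimal image), and
#' the geometry is rebuilt; on failure the Cartesian path is used and
#' flagged in the `coordinate_system` attribute.
#'
#' @param nms `normal_modes`.
#' @param delta displacement vector (length n_f).
#' @param mode "zmatrix" or "cartesian".
#' @param eps finite-difference step along the mode (mass-weighted units).
#' @return structure3d with attribute `coordinate_system`.
#' @export
apply_displacements <- function(nms, delta, mode = c("zmatrix", "cartesian"),
                                eps = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(length(delta) == nms$n_f)
  s <- nms$equilibrium
  x0 <- s$positions
  n <- length(nms$masses)
  invsq <- 1 / sqrt(rep(nms$masses, each = 3L))
  cart <- function() {
    dx <- as.vector(nms$modes %*% delta) * invsq
    s$positions <- x0 + matrix(dx, n, 3L, byrow = TRUE)
    attr(s, "coordinate_system") <- "cartesian"
    s
  }
  if (mode == "cartesian") return(cart())
  res <- tryCatch({
    zt <- zmatrix_topology(s)
    z0 <- zmatrix_coords(zt, x0)
    dz_total <- numeric(length(z0))
    for (i in seq_len(nms$n_f)) {
      qi <- matrix(as.vector(nms$modes[, i]) * invsq, n, 3L, byrow = TRUE)
      zp <- zmatrix_coords(zt, x0 + eps * qi)
      zm <- zmatrix_coords(zt, x0 - eps * qi)
      dzi <- .wrap_z_diff(zp - zm) / (2 * eps)
      dz_total <- dz_total + delta[i] * dzi
    }
    z <- z0 + dz_total
    # wrap dihedrals back into (-180, 180]
    ph <- seq(3L, length(z), by = 3L)
    z[ph] <- ((z[ph] + 180) %% 360) - 180
    if (any(z[seq(1L, length(z), by = 3L)] <= 0, na.rm = TRUE))
      stop("negative bond length after displacement")
    xz <- zmatrix_rebuild(zt, z)
    s$positions <- xz
    attr(s, "coordinate_system") <- "zmatrix"
    s
  }, error = function(e) NULL)
  if (is.null(res)) {
    res <- cart()
    attr(res, "coordinate_system") <- "cartesian_fallback"
  }
  res
}

#' Sample off-equilibrium structures around a conformer
#'
#' Full orchestration: finite-difference Hessian with saddle check,
#' normal-mode analysis, then per sample a temperature/energy draw,
#' energy partition, mode displacements, and geometry application. Every
#' output structure carries its draw provenance as attribute `draw`.
#'
#' @param conf `conformer` (or structure3d at a verified minimum).
#' @param calc calculator.
#' @param n_samples number of structures to generate.
#' @param T_max maximum temperature, K.
#' @param seed RNG seed.
#' @param mode coordinate system for applying displacements.
#' @param h Hessian finite-difference step.
#' @return list of structure3d objects with `draw` attributes.
#' @export
sample_offequilibrium <- function(conf, calc, n_samples, T_max = 1000,
                                  seed = 1L, mode = c("zmatrix", "cartesian"),
                                  h = 1e-3) {
  mode <- match.arg(mode)
  s <- if (inherits(conf, "conformer")) conf$structure else conf
  if (n_samples <= 0L) return(list())
  fd <- finite_difference_hessian(s, calc, h)
  if (!saddle_point_check(fd$stencil_energies, fd$E0))
    stop("conformer rejected: energy does not increase in all stencil directions")
  masses <- element_mass(element_symbol(s$numbers))
  nms <- normal_mode_analysis(fd$H, masses, s)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))

  out <- vector("list", n_samples)
  for (si in seq_len(n_samples)) {
    de <- draw_sample_energy(nms$n_f, T_max)
    pe <- partition_energy(de$E, nms$n_f)
    delta <- mode_displacements(pe$E_vec, nms$k, pe$w)
    st <- apply_displacements(nms, delta, mode)
    attr(st, "draw") <- list(T = de$T, E = de$E, w = pe$w,
                             E_vec = pe$E_vec, delta = delta,
                             coordinate_system = attr(st, "coordinate_system"))
    out[[si]] <- st
  }
  out
}

#' Default per-size sample-count schedule
#'
#' Linear ramp from 100 samples for one heavy atom to 1000 for eight,
#' matching the stated range of 100 to 1000 off-equilibrium structures
#' per conformer.
#'
#' @param n_heavy heavy-atom count.
#' @return integer sample count.
#' @export
sample_count_schedule <- function(n_heavy) {
  n <- pmin(pmax(n_heavy, 1L), 8L)
  as.integer(round(100 + (1000 - 100) * (n - 1L) / 7))
}
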