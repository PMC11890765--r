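# Local geometry optimisation: quasi-Newton (BFGS, inverse-Hessian update)
# with Armijo backtracking, so the energy is monotone non-increasing over
# accepted steps. Two convergence regimes mirror the two-stage workflow:
# the pre-optimisation stops when the energy change per step drops below
# 1 J mol^-1 per atom (robust against pathological starting structures);
# the main stage stops when the maximum per-atom force norm falls below
# 5 meV/A.

.bfgs_minimize <- function(x0, fngr, stop_fn, max_steps) {
  d <- length(x0)
  x <- x0
  r <- fngr(x)
  if (!is.finite(r$energy)) stop("non-finite energy at starting geometry")
  Binv <- diag(d)
  steps <- 0L
  e_prev <- Inf
  repeat {
    if (stop_fn(r, e_prev, steps)) {
      return(list(x = x, energy = r$energy, grad = r$grad, steps = steps,
                  converged = TRUE))
    }
    if (steps >= max_steps) {
      return(list(x = x, energy = r$energy, grad = r$grad, steps = steps,
                  converged = FALSE))
    }
    p <- -as.vector(Binv %*% r$grad)
    gp <- sum(r$grad * p)
    if (gp > 0) {  # not a descent direction; reset
      Binv <- diag(d)
      p <- -r$grad
      gp <- sum(r$grad * p)
    }
    # cap the step length
    pmaxn <- max(abs(p))
    if (pmaxn > 0.3) p <- p * (0.3 / pmaxn)
    gp <- sum(r$grad * p)
    alpha <- 1
    repeat {
      xn <- x + alpha * p
      rn <- fngr(xn)
      if (is.finite(rn$energy) && rn$energy <= r$energy + 1e-4 * alpha * gp)
        break
      alpha <- alpha / 2
      if (alpha < 1e-12) {
        return(list(x = x, energy = r$energy, grad = r$grad, steps = steps,
                    converged = FALSE))
      }
    }
    s <- xn - x
    y <- rn$grad - r$grad
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(d)
      Binv <- (I - rho * outer(s, y)) %*% Binv %*% (I - rho * outer(y, s)) +
        rho * outer(s, s)
    }
    e_prev <- r$energy
    x <- xn
    r <- rn
    steps <- steps + 1L
  }
}

#' Locally optimize a structure
#'
#' @param s structure3d.
#' @param calc calculator supporting energy and forces.
#' @param f_max force-convergence threshold, eV/A (default 5 meV/A).
#' @param max_steps step cap; non-convergence within the cap marks the
#'   result as discarded (`converged = FALSE`) with the reason recorded.
#' @param pre_opt run a pre-optimisation stage first, stopping on an
#'   energy change below 1 J mol^-1 atom^-1 (helps pathological starts).
#' @return object of class `conformer`: list with `structure`, `energy`,
#'   `steps`, `fmax`, `converged`, `reason`.
#' @export
local_optimize <- function(s, calc, f_max = forge_constants$f_max_opt,
                           max_steps = 1000L, pre_opt = FALSE) {
  n <- length(s$numbers)
  fngr <- function(x) {
    st <- s
    st$positions <- matrix(x, ncol = 3L, byrow = TRUE)
    r <- evaluate_calculator(calc, st, c("energy", "forces"))
    list(energy = r$energy, grad = -as.vector(t(r$forces)))
  }
  x <- as.vector(t(s$positions))
  steps_total <- 0L
  if (pre_opt) {
    etol <- forge_constants$e_tol_preopt * n
    pre <- .bfgs_minimize(x, fngr,
                          function(r, e_prev, steps)
                            steps > 0L && abs(e_prev - r$energy) < etol,
                          max_steps = 10000L)
    x <- pre$x
    steps_total <- pre$steps
  }
  stop_force <- function(r, e_prev, steps) {
    fm <- max(sqrt(rowSums(matrix(r$grad, ncol = 3L, byrow = TRUE)^2)))
    fm < f_max
  }
  res <- .bfgs_minimize(x, fngr, stop_force, max_steps)
  st <- s
  st$positions <- matrix(res$x, ncol = 3L, byrow = TRUE)
  fmax <- max(sqrt(rowSums(matrix(res$grad, ncol = 3L, byrow = TRUE)^2)))
  structure(list(structure = st, energy = res$energy,
                 steps = res$steps + steps_total, fmax = fmax,
                 converged = res$converged,
                 reason = if (res$converged) NA_character_
                          else "optimization did not converge"),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> E = ", format(x$energy, digits = 8), " eV, fmax = ",
      format(x$fmax, digits = 3), " eV/A, steps = ", x$steps,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}
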