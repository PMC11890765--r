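# Optimal-superposition RMSD (Kabsch, proper rotations only) and the
# symmetry-aware minimal RMSD over graph automorphisms, optionally
# including the mirror image. Proper rotations ensure enantiomeric
# geometries do not superimpose unless the mirror comparison is requested
# explicitly.

#' RMSD after optimal rigid superposition
#'
#' @param X,Y N x 3 coordinate matrices (same atom order).
#' @return RMSD in the units of the inputs.
#' @export
kabsch_rmsd <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y))
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  sv <- svd(t(Xc) %*% Yc)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
}

# explicit-atom chemgraph (hydrogens as vertices) for automorphism search
.explicit_chemgraph <- function(g) {
  ex <- explicit_atoms(g)
  new_chemgraph(ex$elements, ex$bonds,
                charge = c(ex$charge, rep(0L, length(ex$elements) -
                                            length(ex$charge))),
                h = rep(0L, length(ex$elements)),
                valency = g$valency)
}

#' Symmetry-aware minimal RMSD between two geometries of one molecule
#'
#' Minimum over all graph automorphisms (and, optionally, over the mirror
#' image of `Y`) of the optimal-superposition RMSD. Beyond `cap`
#' automorphisms a heavy-atom-only approximation is used with a warning.
#'
#' @param X,Y N x 3 coordinate matrices in the molecule's atom order.
#' @param g chemgraph of the molecule (hydrogens implicit; geometry rows
#'   must follow [explicit_atoms()] ordering).
#' @param mirror also compare against the mirror image and take the
#'   smaller value.
#' @param cap automorphism cap.
#' @return minimal RMSD.
#' @export
symmetry_rmsd <- function(X, Y, g, mirror = TRUE, cap = 5000L) {
  if (nrow(X) != nrow(Y)) stop("inconsistent atom counts")
  eg <- .explicit_chemgraph(g)
  cg <- .colored_igraph(eg)
  cnt <- igraph::count_isomorphisms(cg$graph, cg$graph,
                                    vertex.color1 = cg$vcol,
                                    vertex.color2 = cg$vcol,
                                    edge.color1 = cg$ecol,
                                    edge.color2 = cg$ecol)
  if (cnt > cap) {
    # heavy-atom-only approximation for very symmetric molecules
    warning("automorphism group of size ", cnt,
            " exceeds cap; heavy-atom-only RMSD")
    nh <- sum(g$atoms$element != "H")
    hauts <- suppressWarnings(graph_automorphisms(g, cap = cap))
    return(.min_rmsd_over(X[seq_len(nh), , drop = FALSE],
                          Y[seq_len(nh), , drop = FALSE], hauts, mirror))
  }
  auts <- graph_automorphisms(eg, cap = cap)
  .min_rmsd_over(X, Y, auts, mirror)
}

.min_rmsd_over <- function(X, Y, auts, mirror) {
  best <- Inf
  Ym <- Y
  Ym[, 3L] <- -Ym[, 3L]
  for (sigma in auts) {
    # sigma[v] = image of v; comparing X with Y re-indexed by sigma
    best <- min(best, kabsch_rmsd(X, Y[sigma, , drop = FALSE]))
    if (mirror)
      best <- min(best, kabsch_rmsd(X, Ym[sigma, , drop = FALSE]))
  }
  best
}
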