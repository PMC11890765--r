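# Z-matrix (internal coordinate) representation: construction order is
# breadth-first from the highest-degree atom; rebuild is the standard
# sequential natural-extension (NeRF) placement. Used by normal-mode
# sampling to apply displacements in internal coordinates, where the
# harmonic approximation survives larger amplitudes than in Cartesians.

# connectivity from covalent radii when no graph is available
.distance_bonds <- function(numbers, x, scale = 1.3) {
  el <- element_symbol(numbers)
  rad <- covalent_radius(el)
  n <- length(numbers)
  bi <- integer(0); bj <- integer(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sqrt(sum((x[i, ] - x[j, ])^2)) < scale * (rad[i] + rad[j])) {
      bi <- c(bi, i); bj <- c(bj, j)
    }
  }
  data.frame(i = bi, j = bj)
}

#' Build a Z-matrix topology for a structure
#'
#' @param s structure3d.
#' @param bonds optional data.frame (i, j); derived from covalent radii
#'   when missing.
#' @return object of class `zmatrix_topology`: BFS atom order plus, for
#'   each placed atom, its distance/angle/dihedral reference atoms.
#' @export
zmatrix_topology <- function(s, bonds = NULL) {
  n <- length(s$numbers)
  x <- s$positions
  if (is.null(bonds)) bonds <- .distance_bonds(s$numbers, x)
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    nb[[bonds$i[k]]] <- c(nb[[bonds$i[k]]], bonds$j[k])
    nb[[bonds$j[k]]] <- c(nb[[bonds$j[k]]], bonds$i[k])
  }
  deg <- lengths(nb)
  root <- which.max(deg)
  ordv <- integer(0)
  parent <- integer(n)
  seen <- logical(n)
  queue <- root
  seen[root] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    ordv <- c(ordv, v)
    for (u in nb[[v]][order(-deg[nb[[v]]])]) if (!seen[u]) {
      seen[u] <- TRUE
      parent[u] <- v
      queue <- c(queue, u)
    }
  }
  if (any(!seen)) stop("disconnected structure; cannot build Z-matrix")
  pos_in_order <- match(seq_len(n), ordv)
  refs <- matrix(0L, n, 3L)  # p (distance), q (angle), r (dihedral)
  for (idx in seq_along(ordv)) {
    if (idx == 1L) next
    v <- ordv[idx]
    p <- parent[v]
    if (p == 0L) stop("tree construction failed")
    placed_before <- function(a) pos_in_order[a] < idx
    q <- parent[p]
    if (q == 0L || !placed_before(q)) {
      cand <- ordv[seq_len(idx - 1L)]
      cand <- setdiff(cand, c(v, p))
      q <- if (length(cand) > 0L) cand[1L] else 0L
    }
    r <- if (q > 0L) parent[q] else 0L
    if (r == 0L || r %in% c(v, p, q) || (r > 0L && !placed_before(r))) {
      cand <- ordv[seq_len(idx - 1L)]
      cand <- setdiff(cand, c(v, p, q))
      r <- if (length(cand) > 0L) cand[1L] else 0L
    }
    refs[v, ] <- c(p, q, r)
  }
  structure(list(order = ordv, refs = refs, n = n),
            class = "zmatrix_topology")
}

#' Internal coordinates of a geometry for a fixed Z-matrix topology
#'
#' @param zt `zmatrix_topology`.
#' @param x N x 3 coordinates.
#' @return numeric vector (r, theta, phi triples in topology order;
#'   angles in degrees), with NA entries for references that do not exist
#'   (first three atoms).
#' @export
zmatrix_coords <- function(zt, x) {
  out <- numeric(0)
  for (idx in seq_along(zt$order)) {
    v <- zt$order[idx]
    p <- zt$refs[v, 1L]; q <- zt$refs[v, 2L]; r <- zt$refs[v, 3L]
    rr <- if (p > 0L) sqrt(sum((x[v, ] - x[p, ])^2)) else NA_real_
    th <- if (q > 0L) {
      a <- x[v, ] - x[p, ]; b <- x[q, ] - x[p, ]
      acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
    } else NA_real_
    ph <- if (r > 0L) dihedral_angle(x, v, p, q, r) else NA_real_
    out <- c(out, rr, th, ph)
  }
  out
}

#' Rebuild Cartesian coordinates from internal coordinates
#'
#' @param zt `zmatrix_topology`.
#' @param z internal-coordinate vector as from [zmatrix_coords()].
#' @return N x 3 coordinate matrix (arbitrary global pose).
#' @export
zmatrix_rebuild <- function(zt, z) {
  n <- zt$n
  x <- matrix(NA_real_, n, 3L)
  for (idx in seq_along(zt$order)) {
    v <- zt$order[idx]
    zr <- z[3L * (idx - 1L) + 1L]
    zth <- z[3L * (idx - 1L) + 2L] * pi / 180
    zph <- z[3L * (idx - 1L) + 3L] * pi / 180
    p <- zt$refs[v, 1L]; q <- zt$refs[v, 2L]; r <- zt$refs[v, 3L]
    if (idx == 1L) {
      x[v, ] <- c(0, 0, 0)
    } else if (idx == 2L) {
      x[v, ] <- x[p, ] + c(zr, 0, 0)
    } else if (idx == 3L || r == 0L) {
      # place in the xz... use an arbitrary frame vector for the dihedral
      A <- if (q > 0L) x[q, ] + c(0, 1, 0) else x[p, ] + c(0, 1, 0)
      ref_q <- if (q > 0L) x[q, ] else x[p, ] + c(1, 0, 0)
      ph <- if (is.na(zph)) 0 else zph
      x[v, ] <- nerf_place(A, ref_q, x[p, ], zr, zth, ph)
    } else {
      x[v, ] <- nerf_place(x[r, ], x[q, ], x[p, ], zr, zth, zph)
    }
  }
  if (any(!is.finite(x))) stop("Z-matrix rebuild produced non-finite coordinates")
  x
}

# wrap dihedral-type entries of an internal-coordinate difference to the
# minimal image (-180, 180]
.wrap_z_diff <- function(dz) {
  ph <- seq(3L, length(dz), by = 3L)
  dz[ph] <- ((dz[ph] + 180) %% 360) - 180
  wrap0 <- dz[ph] == -180
  dz[ph][wrap0] <- 180
  dz
}
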