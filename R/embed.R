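# Initial 3D embedding from simple empirical rules: atoms are placed in
# BFS order with ideal bond lengths (covalent-radius sums), equilibrium
# angles from the hybridisation of the centre, and staggered torsion slots
# with a small random jitter. Ring atoms are laid out as planar polygons
# (interior angle of the smallest ring through the bond, near-zero ring
# dihedrals) so that ring-closure bonds come out near their ideal length;
# the pre-optimisation stage then relaxes everything.

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(c(1, 0, 0))
  v / nv
}

# natural extension of reference frame: place D from A-B-C with bond
# length r(C-D), angle theta(B-C-D) and dihedral phi(A-B-C-D), radians
nerf_place <- function(A, B, C, r, theta, phi) {
  bc <- .unit(C - B)
  nrm <- .unit(.cross3(B - A, bc))
  m <- .cross3(nrm, bc)
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi),
          r * sin(theta) * sin(phi))
  C + d2[1L] * bc + d2[2L] * m + d2[3L] * nrm
}

#' Initial 3D embedding of a chemical graph
#'
#' @param g chemgraph (or SMILES). Hydrogens are made explicit.
#' @param seed integer RNG seed; embeddings are byte-identical under the
#'   same seed.
#' @return structure3d (atom order: heavy atoms in graph order, then
#'   hydrogens grouped after their parents).
#' @export
embed_initial <- function(g, seed = 1L) {
  if (!inherits(g, "chemgraph")) g <- parse_smiles(g)
  ex <- explicit_atoms(g)
  el <- ex$elements
  n <- length(el)
  bonds <- ex$bonds
  rad <- covalent_radius(el)
  es <- assign_electronic_state(ex$graph)

  nb <- vector("list", n)
  omat <- matrix(0, n, n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    omat[i, j] <- bonds$order[k]; omat[j, i] <- bonds$order[k]
  }
  blen <- function(i, j) {
    o <- as.character(omat[i, j])
    (rad[i] + rad[j]) * unname(toyff_params()$r0_scale[o])
  }

  # BFS spanning tree (deterministic)
  parent <- integer(n)
  ordv <- integer(0)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    ordv <- c(ordv, v)
    for (u in nb[[v]]) if (!seen[u]) {
      seen[u] <- TRUE
      parent[u] <- v
      queue <- c(queue, u)
    }
  }

  # ring size per edge from tree-closure cycles (smallest wins)
  ring_size <- matrix(0L, n, n)
  tree_edge <- matrix(FALSE, n, n)
  for (v in seq_len(n)) if (parent[v] > 0L) {
    tree_edge[v, parent[v]] <- TRUE
    tree_edge[parent[v], v] <- TRUE
  }
  path_to_root <- function(v) {
    p <- v
    out <- v
    while (parent[p] > 0L) { p <- parent[p]; out <- c(out, p) }
    out
  }
  for (k in seq_len(nrow(bonds))) {
    u <- bonds$i[k]; w <- bonds$j[k]
    if (tree_edge[u, w]) next
    pu <- path_to_root(u); pw <- path_to_root(w)
    common <- intersect(pu, pw)
    anc <- common[which.min(match(common, pu))]
    cyc <- c(pu[seq_len(match(anc, pu))], rev(pw[seq_len(match(anc, pw) - 1L)]))
    s <- length(cyc)
    for (t in seq_len(s)) {
      a <- cyc[t]; b <- cyc[if (t == s) 1L else t + 1L]
      if (ring_size[a, b] == 0L || s < ring_size[a, b]) {
        ring_size[a, b] <- s; ring_size[b, a] <- s
      }
    }
  }

  theta0 <- function(m, v) {
    # angle at centre m when placing v
    rs <- ring_size[m, v]
    if (rs >= 3L) return(pi - 2 * pi / rs)
    orders <- omat[m, nb[[m]]]
    if (any(orders == 3) || sum(orders >= 2) >= 2L) return(pi)
    if (any(orders >= 1.5)) return(2 * pi / 3)
    acos(-1 / 3)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))

  attempt <- function() {
    x <- matrix(NA_real_, n, 3L)
    placed_children <- vector("list", n)
    for (v in ordv) {
      p <- parent[v]
      if (p == 0L) {
        x[v, ] <- c(0, 0, 0)
      } else if (parent[p] == 0L && length(placed_children[[p]]) == 0L) {
        x[v, ] <- x[p, ] + c(blen(v, p), 0, 0)
      } else {
        gp <- if (parent[p] > 0L) parent[p] else placed_children[[p]][1L]
        ggp_cands <- c(parent[gp], placed_children[[gp]])
        ggp_cands <- ggp_cands[ggp_cands > 0L & ggp_cands != p]
        ggp_cands <- ggp_cands[!is.na(x[ggp_cands, 1L])]
        A <- if (length(ggp_cands) > 0L) x[ggp_cands[1L], ]
             else x[gp, ] + c(0.1, 1, 0)  # arbitrary frame for the torsion
        in_ring <- ring_size[p, v] >= 3L
        slot <- length(placed_children[[p]])
        phi <- if (in_ring) stats::runif(1, -0.05, 0.05)
               else pi + slot * 2 * pi / 3 + stats::runif(1, -0.3, 0.3)
        x[v, ] <- nerf_place(A, x[gp, ], x[p, ], blen(v, p),
                             theta0(p, v), phi)
      }
      if (p > 0L) placed_children[[p]] <- c(placed_children[[p]], v)
    }
    x
  }

  for (try in 1:25) {
    x <- attempt()
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    ok <- min(d) > 0.3
    if (ok) {
      for (k in seq_len(nrow(bonds))) {
        r <- d[bonds$i[k], bonds$j[k]]
        r0 <- blen(bonds$i[k], bonds$j[k])
        if (abs(r - r0) > 0.5 * r0) { ok <- FALSE; break }
      }
    }
    if (ok)
      return(structure3d(element_number(el), x, es$charge, es$multiplicity))
  }
  stop("embedding failed: could not satisfy distance constraints")
}
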