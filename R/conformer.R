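# Conformer search: rotatable-bond detection, a genetic algorithm over
# torsion vectors (population 10, torsion-vector crossover, random
# 60-degree-grid mutations), re-optimisation of every candidate, and
# symmetry-aware greedy deduplication including mirror images.

#' Find rotatable bonds
#'
#' All single bonds between heavy atoms that are rotatable: acyclic bonds
#' whose ends each carry at least one further substituent (hydrogens
#' count, so R-OH and R-CH3 bonds are included), and ring single bonds
#' except in three-membered rings.
#'
#' @param g chemgraph.
#' @return data.frame with columns i, j, ring (logical).
#' @export
find_rotatable_bonds <- function(g) {
  nb <- neighbour_list(g)
  out <- data.frame(i = integer(), j = integer(), ring = logical())
  for (k in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[k] != 1) next
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    if (g$atoms$element[i] == "H" || g$atoms$element[j] == "H") next
    in_ring <- .bond_in_ring(g, i, j)
    if (in_ring) {
      if (length(intersect(nb[[i]], nb[[j]])) > 0L) next  # three-membered
      out <- rbind(out, data.frame(i = i, j = j, ring = TRUE))
    } else {
      subs_i <- length(nb[[i]]) - 1L + g$atoms$h[i]
      subs_j <- length(nb[[j]]) - 1L + g$atoms$h[j]
      if (subs_i >= 1L && subs_j >= 1L)
        out <- rbind(out, data.frame(i = i, j = j, ring = FALSE))
    }
  }
  out
}

#' Dihedral angle
#' @param x N x 3 coordinates.
#' @param i,a,b,j atom indices of the quadruple.
#' @return angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(x, i, a, b, j) {
  b1 <- x[a, ] - x[i, ]
  b2 <- x[b, ] - x[a, ]
  b3 <- x[j, ] - x[b, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# atoms on the j side of bond (a-b), not crossing a
.subtree_atoms <- function(nbl, a, b) {
  seen <- c(a, b)
  stack <- b
  out <- b
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (u in nbl[[v]]) if (!(u %in% seen)) {
      seen <- c(seen, u)
      out <- c(out, u)
      stack <- c(stack, u)
    }
  }
  out
}

# set dihedral (ref_i, a, b, ref_j) to target degrees by rotating the
# b-side subtree about the a->b axis
set_torsion <- function(x, nbl, a, b, ref_i, ref_j, target) {
  cur <- dihedral_angle(x, ref_i, a, b, ref_j)
  delta <- (target - cur) * pi / 180
  axis <- .unit(x[b, ] - x[a, ])
  rot <- .subtree_atoms(nbl, a, b)
  rot <- setdiff(rot, b)
  ct <- cos(delta); st <- sin(delta)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  R <- diag(3L) + st * K + (1 - ct) * (K %*% K)
  for (v in rot) {
    x[v, ] <- as.vector(R %*% (x[v, ] - x[b, ])) + x[b, ]
  }
  x
}

# torsion reference quadruples for the acyclic rotatable bonds of an
# explicit-atom system
.torsion_refs <- function(ex) {
  nbl <- vector("list", length(ex$elements))
  for (k in seq_len(nrow(ex$bonds))) {
    i <- ex$bonds$i[k]; j <- ex$bonds$j[k]
    nbl[[i]] <- c(nbl[[i]], j); nbl[[j]] <- c(nbl[[j]], i)
  }
  rb <- find_rotatable_bonds(ex$graph)
  rb <- rb[!rb$ring, , drop = FALSE]
  refs <- NULL
  for (k in seq_len(nrow(rb))) {
    a <- rb$i[k]; b <- rb$j[k]
    ref_i <- min(setdiff(nbl[[a]], b))
    ref_j <- min(setdiff(nbl[[b]], a))
    refs <- rbind(refs, data.frame(a = a, b = b,
                                   ref_i = ref_i, ref_j = ref_j))
  }
  list(refs = refs, nbl = nbl)
}

#' Genetic conformer search
#'
#' Evolves a population of torsion vectors over the acyclic rotatable
#' bonds (population size `n_conformers`, crossover mixes parent torsion
#' vectors, mutation resets a torsion to a random multiple of 60 degrees),
#' re-optimises every candidate with [local_optimize()] and returns the
#' deduplicated set of distinct conformers, the starting basin included.
#'
#' @param c0 optimized starting conformer (from [local_optimize()]).
#' @param calc calculator.
#' @param g chemgraph of the molecule.
#' @param n_conformers population size (default 10).
#' @param generations number of GA generations (default 30).
#' @param seed RNG seed.
#' @param rmsd_threshold duplicate threshold, Angstrom.
#' @return list of `conformer` objects, sorted by energy.
#' @export
conformer_search <- function(c0, calc, g, n_conformers = 10L,
                             generations = 30L, seed = 1L,
                             rmsd_threshold = forge_constants$rmsd_dup) {
  if (!inherits(g, "chemgraph")) g <- parse_smiles(g)
  ex <- explicit_atoms(g)
  tr <- .torsion_refs(ex)
  if (is.null(tr$refs) || nrow(tr$refs) == 0L)
    return(deduplicate(list(c0), g, rmsd_threshold))
  nrot <- nrow(tr$refs)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))

  grid <- seq(-120, 180, by = 60)
  x0 <- c0$structure$positions
  base_tor <- vapply(seq_len(nrot), function(k)
    dihedral_angle(x0, tr$refs$ref_i[k], tr$refs$a[k], tr$refs$b[k],
                   tr$refs$ref_j[k]), numeric(1))

  memo <- new.env(parent = emptyenv())
  evaluate <- function(tv) {
    key <- paste(round(tv / 15), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    x <- x0
    for (k in seq_len(nrot)) {
      x <- set_torsion(x, tr$nbl, tr$refs$a[k], tr$refs$b[k],
                       tr$refs$ref_i[k], tr$refs$ref_j[k], tv[k])
    }
    # tiny jitter breaks the symmetry of exactly eclipsed/staggered grid
    # starts, so the optimizer cannot sit down on a saddle point
    x <- x + matrix(stats::rnorm(length(x), sd = 5e-3), nrow(x), 3L)
    s <- c0$structure
    s$positions <- x
    opt <- tryCatch(local_optimize(s, calc), error = function(e) NULL)
    memo[[key]] <- opt
    opt
  }

  pop <- c(list(base_tor), lapply(seq_len(n_conformers - 1L), function(k)
    sample(grid, nrot, replace = TRUE)))
  results <- list()
  add_result <- function(opt) {
    if (!is.null(opt) && opt$converged)
      results[[length(results) + 1L]] <<- opt
  }
  for (tv in pop) add_result(evaluate(tv))

  for (gen in seq_len(generations)) {
    children <- lapply(seq_len(n_conformers), function(k) {
      pa <- pop[[sample.int(length(pop), 1L)]]
      pb <- pop[[sample.int(length(pop), 1L)]]
      mask <- stats::runif(nrot) < 0.5
      child <- ifelse(mask, pa, pb)
      mut <- stats::runif(nrot) < 0.3
      child[mut] <- sample(grid, sum(mut), replace = TRUE)
      child
    })
    for (tv in children) add_result(evaluate(tv))
    # diversity selection: keep the starting vector plus the most
    # mutually distant torsion vectors seen so far
    pool <- unique(c(pop, children))
    if (length(pool) > n_conformers) {
      keep <- list(pool[[1L]])
      pool <- pool[-1L]
      while (length(keep) < n_conformers && length(pool) > 0L) {
        dmin <- vapply(pool, function(tv) {
          min(vapply(keep, function(kv) {
            dd <- abs(tv - kv) %% 360
            sqrt(sum(pmin(dd, 360 - dd)^2))
          }, numeric(1)))
        }, numeric(1))
        pick <- which.max(dmin)
        keep[[length(keep) + 1L]] <- pool[[pick]]
        pool <- pool[-pick]
      }
      pop <- keep
    } else {
      pop <- pool
    }
  }

  # starting basin first, then by energy
  results <- c(list(c0), results)
  ord <- order(vapply(results, `[[`, numeric(1), "energy"))
  first <- which(vapply(results, identical, logical(1), results[[1L]]))[1L]
  results <- results[c(first, setdiff(ord, first))]
  kept <- deduplicate(results, g, rmsd_threshold)
  Filter(function(cf) is_pes_minimum(calc, cf$structure), kept)
}

#' Check that a structure is a PES minimum (not a saddle point)
#'
#' Eigenvalue test on the Hessian: a converged geometry whose Hessian has
#' a significantly negative eigenvalue is a saddle point. Uses the
#' analytic Hessian when the calculator provides one, a central-difference
#' Hessian of the forces otherwise.
#'
#' @param calc calculator.
#' @param s structure3d at a force-converged geometry.
#' @param tol negative-eigenvalue tolerance (eV/A^2).
#' @return logical.
#' @export
is_pes_minimum <- function(calc, s, tol = 1e-4) {
  H <- tryCatch(analytic_hessian(calc, s), error = function(e) NULL)
  if (is.null(H)) {
    h <- 1e-3
    n3 <- 3L * length(s$numbers)
    H <- matrix(0, n3, n3)
    for (k in seq_len(n3)) {
      a <- (k - 1L) %/% 3L + 1L
      c3 <- (k - 1L) %% 3L + 1L
      sp <- s; sp$positions[a, c3] <- sp$positions[a, c3] + h
      sm <- s; sm$positions[a, c3] <- sm$positions[a, c3] - h
      fp <- evaluate_calculator(calc, sp, "forces")$forces
      fm <- evaluate_calculator(calc, sm, "forces")$forces
      H[, k] <- -as.vector(t(fp - fm)) / (2 * h)
    }
    H <- (H + t(H)) / 2
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  # six (five for linear) rigid-body eigenvalues are ~0; anything clearly
  # negative marks a saddle
  all(ev > -tol * max(abs(ev), 1))
}

#' Deduplicate conformers by symmetry-aware RMSD
#'
#' Greedy keep-first clustering in input order: a conformer is a
#' duplicate if its minimal RMSD (over graph automorphisms, optimal
#' superposition, and the mirror image) to any kept conformer is below
#' the threshold.
#'
#' @param confs list of `conformer` objects sharing the atom ordering of
#'   one molecule.
#' @param g chemgraph of the molecule.
#' @param rmsd_threshold duplicate threshold, Angstrom (default 0.05).
#' @param mirror compare mirror images too (default TRUE).
#' @return list of kept conformers, input order preserved.
#' @export
deduplicate <- function(confs, g, rmsd_threshold = forge_constants$rmsd_dup,
                        mirror = TRUE) {
  if (!inherits(g, "chemgraph")) g <- parse_smiles(g)
  n_atoms <- unique(vapply(confs, function(cf) nrow(cf$structure$positions),
                           integer(1)))
  if (length(n_atoms) > 1L) stop("inconsistent atom counts")
  kept <- list()
  for (cf in confs) {
    dup <- FALSE
    for (kf in kept) {
      r <- symmetry_rmsd(kf$structure$positions, cf$structure$positions,
                         g, mirror = mirror)
      if (r < rmsd_threshold) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- cf
  }
  kept
}
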