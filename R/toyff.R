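# Analytic toy force field: harmonic bonds, cosine-harmonic angles,
# cosine torsions, exponential non-bonded repulsion, and a distance-decay
# bond-order model. Parameters derive from the molecular graph (reference
# bond lengths from covalent-radius sums), so bond-order quality checks
# pass at equilibrium by construction. All terms are smooth algebraic
# expressions in Cartesian coordinates; energies, gradients and Hessians
# come from symbolically differentiated term functions, so the "analytic"
# Hessian is exact and independent of any finite-difference code.

.term_fns <- local({
  cache <- NULL
  vnames <- function(k) as.vector(vapply(seq_len(k), function(i)
    paste0(c("x", "y", "z"), i), character(3)))
  build <- function() {
    v2 <- vnames(2L); v3 <- vnames(3L); v4 <- vnames(4L)
    bond <- ~ 0.5 * kb *
      (sqrt((x1 - x2)^2 + (y1 - y2)^2 + (z1 - z2)^2) - r0)^2
    rep_ <- ~ sc * A *
      exp(-B * sqrt((x1 - x2)^2 + (y1 - y2)^2 + (z1 - z2)^2))
    # angle at atom 2 between atoms 1 and 3, cosine-harmonic
    u <- paste0(
      "((x1-x2)*(x3-x2)+(y1-y2)*(y3-y2)+(z1-z2)*(z3-z2))/",
      "(sqrt((x1-x2)^2+(y1-y2)^2+(z1-z2)^2)*",
      "sqrt((x3-x2)^2+(y3-y2)^2+(z3-z2)^2))")
    angle <- stats::as.formula(paste0("~ 0.5 * ka * (", u, " - c0)^2"))
    angle_lin <- stats::as.formula(paste0("~ ka * (1 + ", u, ")"))
    # torsion 1-2-3-4: cosine of the dihedral from the two plane normals
    cr <- function(ax, ay, az, bx, by, bz)
      c(paste0("(", ay, ")*(", bz, ")-(", az, ")*(", by, ")"),
        paste0("(", az, ")*(", bx, ")-(", ax, ")*(", bz, ")"),
        paste0("(", ax, ")*(", by, ")-(", ay, ")*(", bx, ")"))
    b1 <- c("x2-x1", "y2-y1", "z2-z1")
    b2 <- c("x3-x2", "y3-y2", "z3-z2")
    b3 <- c("x4-x3", "y4-y3", "z4-z3")
    n1 <- cr(b1[1], b1[2], b1[3], b2[1], b2[2], b2[3])
    n2 <- cr(b2[1], b2[2], b2[3], b3[1], b3[2], b3[3])
    dot <- function(a, b) paste0("(", a, ")*(", b, ")", collapse = "+")
    cphi <- paste0("(", dot(n1, n2), ")/sqrt((", dot(n1, n1), ")*(",
                   dot(n2, n2), ")+1e-24)")
    tor3 <- stats::as.formula(paste0(
      "~ 0.5 * V * (1 + 4*(", cphi, ")^3 - 3*(", cphi, "))"))
    tor2 <- stats::as.formula(paste0("~ V * (1 - (", cphi, ")^2)"))
    list(
      bond = stats::deriv3(bond, v2, c(v2, "kb", "r0")),
      rep = stats::deriv3(rep_, v2, c(v2, "sc", "A", "B")),
      angle = stats::deriv3(angle, v3, c(v3, "ka", "c0")),
      angle_lin = stats::deriv3(angle_lin, v3, c(v3, "ka")),
      tor3 = stats::deriv3(tor3, v4, c(v4, "V")),
      tor2 = stats::deriv3(tor2, v4, c(v4, "V"))
    )
  }
  function() {
    if (is.null(cache)) cache <<- build()
    cache
  }
})

#' Default toy-force-field parameters
#' @return named list of parameters (eV / Angstrom units).
#' @export
toyff_params <- function() {
  list(
    kb = c("1" = 25, "1.5" = 30, "2" = 35, "3" = 45),  # eV/A^2
    r0_scale = c("1" = 1.00, "1.5" = 0.93, "2" = 0.87, "3" = 0.78),
    ka = 3.0,          # eV (cosine-harmonic angle stiffness)
    V3 = 0.02,         # eV per torsion quadruple, 3-fold
    V2 = 1.0,          # eV per torsion quadruple, 2-fold (planarity)
    A_rep = 10.0,      # eV
    B_rep = 3.0,       # 1/A
    scale14 = 0.5,     # 1-4 repulsion scaling
    alpha_bo = 2.0,    # 1/A, bond-order decay
    well = 4.0         # eV, per-bond atomization well depth
  )
}

# expand a chemical graph to explicit atoms: heavy atoms in graph order,
# then hydrogens appended after their parents
explicit_atoms <- function(g, kekulize = TRUE) {
  if (kekulize) g <- kekulize(g)
  el <- g$atoms$element
  bonds <- g$bonds
  nheavy <- length(el)
  parent_of_h <- integer(0)
  for (v in seq_len(nheavy)) {
    nh <- g$atoms$h[v]
    if (nh > 0L) {
      idx <- length(el) + seq_len(nh)
      el <- c(el, rep("H", nh))
      bonds <- rbind(bonds, data.frame(i = rep(v, nh), j = idx,
                                       order = rep(1, nh)))
      parent_of_h <- c(parent_of_h, rep(v, nh))
    }
  }
  list(elements = el, bonds = bonds, n_heavy = nheavy,
       charge = g$atoms$charge, graph = g)
}

#' Build the analytic toy force field for a molecule
#'
#' @param g chemgraph (or SMILES string). Aromatic graphs are kekulized.
#' @param params parameter list, see [toyff_params()].
#' @return calculator object of class `toy_forcefield` with capabilities
#'   energy, forces, bond_orders and partial_charges.
#' @export
toy_forcefield <- function(g, params = toyff_params()) {
  if (!inherits(g, "chemgraph")) g <- parse_smiles(g)
  ex <- explicit_atoms(g)
  el <- ex$elements
  n <- length(el)
  bonds <- ex$bonds
  rad <- covalent_radius(el)

  okey <- as.character(bonds$order)
  bterms <- data.frame(
    i = bonds$i, j = bonds$j,
    kb = unname(params$kb[okey]),
    r0 = (rad[bonds$i] + rad[bonds$j]) * unname(params$r0_scale[okey]))

  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    nb[[bonds$i[k]]] <- c(nb[[bonds$i[k]]], bonds$j[k])
    nb[[bonds$j[k]]] <- c(nb[[bonds$j[k]]], bonds$i[k])
  }
  omat <- matrix(0, n, n)
  for (k in seq_len(nrow(bonds))) {
    omat[bonds$i[k], bonds$j[k]] <- bonds$order[k]
    omat[bonds$j[k], bonds$i[k]] <- bonds$order[k]
  }

  # hybridisation-dependent equilibrium angle at each centre
  cos0 <- function(m) {
    orders <- omat[m, nb[[m]]]
    if (any(orders == 3) || sum(orders >= 2) >= 2L) return(NA_real_)  # linear
    if (any(orders >= 1.5)) return(-0.5)       # trigonal, 120 deg
    -1 / 3                                      # tetrahedral, 109.47 deg
  }
  ai <- integer(0); am <- integer(0); aj <- integer(0); ac0 <- numeric(0)
  for (m in seq_len(n)) {
    ns <- nb[[m]]
    if (length(ns) < 2L) next
    c0 <- cos0(m)
    prs <- utils::combn(ns, 2L)
    for (p in seq_len(ncol(prs))) {
      ai <- c(ai, prs[1L, p]); am <- c(am, m); aj <- c(aj, prs[2L, p])
      ac0 <- c(ac0, c0)
    }
  }
  aterms <- data.frame(i = ai, m = am, j = aj, c0 = ac0,
                       ka = rep(params$ka, length(ai)))

  ti <- integer(0); ta <- integer(0); tb <- integer(0); tj <- integer(0)
  tV <- numeric(0); tn <- integer(0)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$i[k]; b <- bonds$j[k]; o <- bonds$order[k]
    if (o == 3) next
    for (i in setdiff(nb[[a]], b)) for (j in setdiff(nb[[b]], a)) {
      if (i == j) next
      ti <- c(ti, i); ta <- c(ta, a); tb <- c(tb, b); tj <- c(tj, j)
      if (o == 1) { tV <- c(tV, params$V3); tn <- c(tn, 3L) }
      else { tV <- c(tV, params$V2); tn <- c(tn, 2L) }
    }
  }
  tterms <- data.frame(i = ti, a = ta, b = tb, j = tj, V = tV, nfold = tn)

  # non-bonded repulsion: graph distance >= 3 (1-4 scaled)
  gd <- matrix(Inf, n, n)
  diag(gd) <- 0
  for (k in seq_len(nrow(bonds))) {
    gd[bonds$i[k], bonds$j[k]] <- 1
    gd[bonds$j[k], bonds$i[k]] <- 1
  }
  for (via in seq_len(n)) {
    gd <- pmin(gd, outer(gd[, via], gd[via, ], `+`))
  }
  ri <- integer(0); rj <- integer(0); rs <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (gd[i, j] <= 2) next
    ri <- c(ri, i); rj <- c(rj, j)
    rs <- c(rs, if (gd[i, j] == 3) params$scale14 else 1)
  }
  rterms <- data.frame(i = ri, j = rj, sc = rs)

  structure(list(elements = el, numbers = element_number(el),
                 masses = element_mass(el),
                 bonds = bonds, n_heavy = ex$n_heavy,
                 graph = ex$graph, charge_per_atom = ex$charge,
                 bterms = bterms, aterms = aterms, tterms = tterms,
                 rterms = rterms, params = params),
            class = c("toy_forcefield", "forge_calculator"))
}

#' @export
calculator_capabilities.toy_forcefield <- function(calc) {
  c("energy", "forces", "bond_orders", "partial_charges")
}

# accumulate one family of symbolically differentiated terms
.acc_terms <- function(fn, args, idx_atoms, n, grad = TRUE, hess = FALSE) {
  val <- do.call(fn, args)
  k <- length(val)
  nat <- ncol(idx_atoms)   # atoms per term
  out <- list(energy = sum(val))
  if (grad) {
    gr <- attr(val, "gradient")
    G <- matrix(0, n, 3L)
    for (t in seq_len(k)) for (a in seq_len(nat)) {
      at <- idx_atoms[t, a]
      G[at, ] <- G[at, ] + gr[t, (3L * a - 2L):(3L * a)]
    }
    out$grad <- G
  }
  if (hess) {
    hs <- attr(val, "hessian")
    H <- matrix(0, 3L * n, 3L * n)
    for (t in seq_len(k)) {
      ids <- as.vector(vapply(idx_atoms[t, ], function(a)
        (3L * a - 2L):(3L * a), integer(3)))
      H[ids, ids] <- H[ids, ids] + hs[t, , ]
    }
    out$hess <- H
  }
  out
}

# evaluate all term families; internal workhorse
.toy_eval <- function(calc, x, grad = TRUE, hess = FALSE) {
  fns <- .term_fns()
  n <- nrow(x)
  energy <- 0
  G <- matrix(0, n, 3L)
  H <- if (hess) matrix(0, 3L * n, 3L * n) else NULL
  coords <- function(idx) {
    args <- list()
    for (a in seq_len(ncol(idx))) {
      args[[paste0("x", a)]] <- x[idx[, a], 1L]
      args[[paste0("y", a)]] <- x[idx[, a], 2L]
      args[[paste0("z", a)]] <- x[idx[, a], 3L]
    }
    args
  }
  run <- function(fn, idx, extra) {
    if (nrow(idx) == 0L) return()
    r <- .acc_terms(fn, c(coords(idx), extra), idx, n, grad, hess)
    energy <<- energy + r$energy
    if (grad) G <<- G + r$grad
    if (hess) H <<- H + r$hess
  }
  bt <- calc$bterms
  run(fns$bond, cbind(bt$i, bt$j), list(kb = bt$kb, r0 = bt$r0))
  at <- calc$aterms
  lin <- is.na(at$c0)
  if (any(!lin)) {
    a1 <- at[!lin, ]
    run(fns$angle, cbind(a1$i, a1$m, a1$j), list(ka = a1$ka, c0 = a1$c0))
  }
  if (any(lin)) {
    a2 <- at[lin, ]
    run(fns$angle_lin, cbind(a2$i, a2$m, a2$j), list(ka = a2$ka))
  }
  tt <- calc$tterms
  t3 <- tt[tt$nfold == 3L, ]
  t2 <- tt[tt$nfold == 2L, ]
  if (nrow(t3) > 0L)
    run(fns$tor3, cbind(t3$i, t3$a, t3$b, t3$j), list(V = t3$V))
  if (nrow(t2) > 0L)
    run(fns$tor2, cbind(t2$i, t2$a, t2$b, t2$j), list(V = t2$V))
  rt <- calc$rterms
  run(fns$rep, cbind(rt$i, rt$j),
      list(sc = rt$sc, A = calc$params$A_rep, B = calc$params$B_rep))
  # constant atomization offset: each bond sits in a well so formation
  # energies are negative near equilibrium and positive when stretched far
  energy <- energy - calc$params$well * nrow(calc$bonds)
  list(energy = energy, grad = G, hess = H)
}

#' Toy bond orders
#'
#' BO(i,j) = n_ij * exp(-alpha * (r_ij - r0_ij)) clipped to [0, n_ij + 1]
#' for bonded pairs of nominal order n_ij, zero for non-bonded pairs.
#'
#' @param calc toy force field.
#' @param s structure3d.
#' @return symmetric N x N matrix with zero diagonal.
#' @export
toy_bond_orders <- function(calc, s) {
  n <- length(calc$elements)
  bo <- matrix(0, n, n)
  al <- calc$params$alpha_bo
  for (k in seq_len(nrow(calc$bonds))) {
    i <- calc$bonds$i[k]; j <- calc$bonds$j[k]
    nom <- calc$bonds$order[k]
    r <- sqrt(sum((s$positions[i, ] - s$positions[j, ])^2))
    v <- min(max(nom * exp(-al * (r - calc$bterms$r0[k])), 0), nom + 1)
    bo[i, j] <- v
    bo[j, i] <- v
  }
  bo
}

#' @export
evaluate_calculator.toy_forcefield <- function(calc, s,
    properties = c("energy", "forces")) {
  stopifnot(length(s$numbers) == length(calc$elements))
  r <- .toy_eval(calc, s$positions,
                 grad = "forces" %in% properties, hess = FALSE)
  out <- list()
  if ("energy" %in% properties) out$energy <- r$energy
  if ("forces" %in% properties) out$forces <- -r$grad
  if ("bond_orders" %in% properties) out$bond_orders <- toy_bond_orders(calc, s)
  if ("partial_charges" %in% properties)
    out$charges <- c(as.numeric(calc$charge_per_atom),
                     rep(0, length(calc$elements) - length(calc$charge_per_atom)))
  out
}

#' @export
analytic_hessian.toy_forcefield <- function(calc, s) {
  H <- .toy_eval(calc, s$positions, grad = FALSE, hess = TRUE)$hess
  (H + t(H)) / 2
}

#' Reference structure3d for a toy force field
#'
#' Convenience: an embedded, unoptimized starting structure for the
#' molecule the force field was built from (see [embed_initial()]).
#'
#' @param calc toy force field.
#' @param seed RNG seed for the embedding.
#' @return structure3d.
#' @export
toy_structure <- function(calc, seed = 1L) {
  embed_initial(calc$graph, seed = seed)
}
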