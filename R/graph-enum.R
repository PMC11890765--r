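# Systematic enumeration of small chemical graphs: connected simple graphs
# up to isomorphism, bond-multiplicity expansion (orders 1-3, vertex degree
# capped at six), and element labelling under valency constraints.
#
# Isomorphism dedup is done by an explicit canonical form over all vertex
# permutations; at <= 6 vertices (<= 720 permutations) nothing faster is
# needed, and the independent test oracle uses igraph instead.

# canonical key of a (multi)graph: lexicographically smallest row-major
# upper-triangle weight string over all vertex permutations
.canon_key <- function(n, adj) {
  if (n == 1L) return("1")
  perms <- .permutations(n)
  best <- NULL
  ut <- which(upper.tri(matrix(0, n, n)))
  for (p in perms) {
    a <- adj[p, p, drop = FALSE]
    key <- paste(a[ut], collapse = ",")
    if (is.null(best) || key < best) best <- key
  }
  best
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

.adj_from_edges <- function(n, edges, w = NULL) {
  a <- matrix(0L, n, n)
  if (nrow(edges) > 0L) {
    ww <- if (is.null(w)) rep(1L, nrow(edges)) else w
    for (k in seq_len(nrow(edges))) {
      a[edges$i[k], edges$j[k]] <- ww[k]
      a[edges$j[k], edges$i[k]] <- ww[k]
    }
  }
  a
}

.is_connected_adj <- function(a) {
  n <- nrow(a)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (u in which(a[v, ] > 0L & !seen)) {
      seen[u] <- TRUE
      stack <- c(stack, u)
    }
  }
  all(seen)
}

#' Enumerate connected simple graphs up to isomorphism
#'
#' @param max_vertices maximum number of vertices (1..6; default 5).
#' @return list of graphs, each a list with `n` and `edges` (data.frame
#'   i, j); exactly one representative per isomorphism class, all sizes
#'   from 1 to `max_vertices`.
#' @export
enumerate_connected_simple_graphs <- function(max_vertices = 5L) {
  if (!is.numeric(max_vertices) || max_vertices < 1 || max_vertices > 6)
    stop("max_vertices must be between 1 and 6")
  max_vertices <- as.integer(max_vertices)
  out <- list()
  for (n in seq_len(max_vertices)) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    m <- nrow(pairs)
    seen <- new.env(parent = emptyenv())
    for (mask in 0:(2^m - 1L)) {
      sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L
      if (n > 1L && sum(sel) < n - 1L) next
      edges <- data.frame(i = pairs[sel, 1L], j = pairs[sel, 2L])
      a <- .adj_from_edges(n, edges)
      if (!.is_connected_adj(a)) next
      key <- .canon_key(n, a)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- list(n = n, edges = edges)
      }
      if (m == 0L) break
    }
  }
  out
}

#' Expand a simple graph into bond-order multigraphs
#'
#' Every edge receives a multiplicity of 1, 2 or 3 (zero to two extra
#' edges between the same vertices); assignments where any vertex degree
#' (counting multiplicity) exceeds six are discarded, and the survivors
#' are deduplicated up to isomorphism.
#'
#' @param g simple graph (list with `n`, `edges`).
#' @param max_degree degree cap (default 6).
#' @return list of multigraphs (`n`, `edges`, `mult`).
#' @export
expand_bond_orders <- function(g, max_degree = 6L) {
  m <- nrow(g$edges)
  if (m == 0L) return(list(list(n = g$n, edges = g$edges, mult = integer(0))))
  grid <- as.matrix(expand.grid(rep(list(1:3), m)))
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (r in seq_len(nrow(grid))) {
    w <- as.integer(grid[r, ])
    a <- .adj_from_edges(g$n, g$edges, w)
    if (any(rowSums(a) > max_degree)) next
    key <- .canon_key(g$n, a)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- list(n = g$n, edges = g$edges, mult = w)
    }
  }
  out
}

#' Label multigraph vertices with elements
#'
#' All element assignments for which every vertex degree (with
#' multiplicity) stays within the element's maximum valency; hydrogens are
#' implicit (filled to valency). Results are canonical SMILES,
#' deduplicated.
#'
#' @param mg multigraph (`n`, `edges`, `mult`).
#' @param elements candidate element symbols (default: organic subset).
#' @param valency valency table.
#' @return character vector of canonical SMILES.
#' @export
label_elements <- function(mg, elements = organic_subset(),
                           valency = default_valency()) {
  n <- mg$n
  deg <- numeric(n)
  if (length(mg$mult) > 0L) {
    for (k in seq_len(nrow(mg$edges))) {
      deg[mg$edges$i[k]] <- deg[mg$edges$i[k]] + mg$mult[k]
      deg[mg$edges$j[k]] <- deg[mg$edges$j[k]] + mg$mult[k]
    }
  }
  ok_by_vertex <- lapply(seq_len(n), function(v) {
    elements[valency[elements] >= deg[v]]
  })
  if (any(vapply(ok_by_vertex, length, integer(1)) == 0L)) return(character(0))
  combos <- expand.grid(ok_by_vertex, stringsAsFactors = FALSE)
  out <- character(0)
  for (r in seq_len(nrow(combos))) {
    el <- as.character(unlist(combos[r, ]))
    bonds <- data.frame(i = mg$edges$i, j = mg$edges$j,
                        order = as.numeric(mg$mult))
    if (length(mg$mult) == 0L)
      bonds <- data.frame(i = integer(), j = integer(), order = numeric())
    g <- new_chemgraph(el, bonds, valency = valency)
    out <- c(out, canonical_smiles(g))
  }
  sort(unique(out))
}

#' Full graph-enumeration cascade
#'
#' Connected simple graphs, bond-order expansion, element labelling;
#' output is the duplicate-free set of canonical SMILES.
#'
#' @inheritParams enumerate_connected_simple_graphs
#' @inheritParams label_elements
#' @return character vector of canonical SMILES.
#' @export
enumerate_chemical_space <- function(max_vertices = 5L,
                                     elements = organic_subset(),
                                     valency = default_valency()) {
  out <- character(0)
  for (g in enumerate_connected_simple_graphs(max_vertices)) {
    for (mg in expand_bond_orders(g)) {
      out <- c(out, label_elements(mg, elements, valency))
    }
  }
  sort(unique(out))
}
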