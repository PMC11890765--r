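# SMILES writer. Emits a molecule as a SMILES string following a DFS whose
# branch order is dictated by per-atom ranks (canonical ranks for canonical
# output, input order otherwise). Tetrahedral parities and cis/trans
# descriptors are re-derived for the emitted neighbour order, so the same
# abstract molecule always yields the same stereo marks for a given rank
# vector.

perm_sign <- function(p) {
  s <- 1L
  n <- length(p)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    if (p[a] > p[b]) s <- -s
  s
}

neighbour_list <- function(g) {
  n <- nrow(g$atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

bond_lookup <- function(g) {
  if (nrow(g$bonds) == 0L) return(function(i, j) NULL)
  ord <- structure(as.list(g$bonds$order),
                   names = paste0(pmin(g$bonds$i, g$bonds$j), "_",
                                  pmax(g$bonds$i, g$bonds$j)))
  function(i, j) ord[[paste0(min(i, j), "_", max(i, j))]]
}

#' Write a chemical graph as a SMILES string
#'
#' @param g chemgraph.
#' @param ranks integer vector of per-atom priorities controlling traversal
#'   order (lower rank is visited first); defaults to input order.
#' @return SMILES string.
#' @export
write_smiles <- function(g, ranks = NULL) {
  n <- nrow(g$atoms)
  if (is.null(ranks)) ranks <- seq_len(n)
  nb <- neighbour_list(g)
  border <- bond_lookup(g)

  parent <- integer(n)
  children <- vector("list", n)
  pre <- integer(n)     # preorder position
  visited <- logical(n)
  backs <- list()       # back edges as c(i, j), i seen first
  cnt <- 0L

  root <- which.min(ranks)
  dfs <- function(v, p) {
    visited[v] <<- TRUE
    cnt <<- cnt + 1L
    pre[v] <<- cnt
    parent[v] <<- p
    ns <- nb[[v]]
    ns <- ns[ns != p]
    ns <- ns[order(ranks[ns])]
    for (u in ns) {
      if (visited[u]) {
        k <- paste0(min(v, u), "_", max(v, u))
        if (is.null(backs[[k]])) backs[[k]] <<- c(u, v)  # u opened first
      } else {
        children[[v]] <<- c(children[[v]], u)
        dfs(u, v)
      }
    }
  }
  dfs(root, 0L)
  if (any(!visited)) stop("graph is disconnected; cannot write SMILES")

  # ring digits: for each back edge, opened at the endpoint seen first
  ring_open <- vector("list", n)   # at atom -> list of (other, digit)
  ring_close <- vector("list", n)
  if (length(backs) > 0L) {
    ord <- order(vapply(backs, function(e) pre[e[1L]] * (n + 1L) + pre[e[2L]],
                        numeric(1)))
    backs <- backs[ord]
    free <- rep(TRUE, 99L)
    digit_of <- integer(0)
    closing_at <- vapply(backs, function(e) e[2L], integer(1))
    opening_at <- vapply(backs, function(e) e[1L], integer(1))
    # assign digits greedily in opening order, reusing freed digits
    events <- data.frame(idx = seq_along(backs), open = opening_at,
                         close = closing_at)
    digits <- integer(length(backs))
    # process atoms in preorder; at each atom first close, then open
    for (v in order(pre)[seq_len(n)]) {
      for (e in which(events$close == v)) {
        if (digits[e] > 0L) free[digits[e]] <- TRUE
      }
      for (e in which(events$open == v)) {
        d <- which(free)[1L]
        digits[e] <- d
        free[d] <- FALSE
      }
      # closes free digits only after both uses; simpler: free on close below
    }
    # The loop above frees before assigning at the same atom which is fine.
    for (e in seq_along(backs)) {
      u <- backs[[e]][1L]; v <- backs[[e]][2L]
      ring_open[[u]] <- c(ring_open[[u]], list(list(other = v, digit = digits[e])))
      ring_close[[v]] <- c(ring_close[[v]], list(list(other = u, digit = digits[e])))
    }
  }

  # output neighbour order per atom (for stereo): parent, implicit H,
  # ring closures then ring openings (emission order), then children
  ring_nbrs <- function(v) {
    cl <- ring_close[[v]]
    op <- ring_open[[v]]
    cl <- cl[order(vapply(cl, function(x) x$digit, integer(1)))]
    c(vapply(cl, function(x) x$other, integer(1)),
      vapply(op, function(x) x$other, integer(1)))
  }

  stereo_atom_of <- integer(n)
  if (length(g$stereo_atoms) > 0L)
    for (s in seq_along(g$stereo_atoms))
      stereo_atom_of[g$stereo_atoms[[s]]$atom] <- s

  # directional flags for cis/trans: map bond key -> dir written low->high
  dirflag <- new.env(parent = emptyenv())
  bkey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  get_dir <- function(u, v) {
    d <- dirflag[[bkey(u, v)]]
    if (is.null(d)) return(0L)
    if (u < v) d else -d
  }
  set_dir <- function(u, v, d) {
    assign(bkey(u, v), if (u < v) d else -d, envir = dirflag)
  }
  # normalise each stereo-bond record by rank so the emitted '/' and '\'
  # marks are a function of the ranks alone (not of parse order)
  sbs <- lapply(g$stereo_bonds, function(sb) {
    if (ranks[sb$j] < ranks[sb$i]) {
      sb <- list(i = sb$j, j = sb$i, ref_i = sb$ref_j, ref_j = sb$ref_i,
                 same_side = sb$same_side)
    }
    for (end in c("i", "j")) {
      v <- sb[[end]]
      other <- if (end == "i") sb$j else sb$i
      reff <- if (end == "i") "ref_i" else "ref_j"
      cand <- setdiff(nb[[v]], other)
      pick <- cand[which.min(ranks[cand])]
      if (pick != sb[[reff]]) {           # other substituent: opposite side
        sb[[reff]] <- pick
        sb$same_side <- !sb$same_side
      }
    }
    sb
  })
  if (length(sbs) > 0L)
    sbs <- sbs[order(vapply(sbs, function(s) ranks[s$i], integer(1)))]
  # Each stereo bond couples the direction flags of its two reference
  # single bonds: d(j->b) = -d(a->i) for cis, +d(a->i) for trans. Shared
  # flags (conjugated systems) make this a parity constraint graph; solve
  # by propagation, seeding each component with +1 in deterministic order.
  repeat {
    progressed <- FALSE
    unresolved <- FALSE
    for (sb in sbs) {
      a <- sb$ref_i; i <- sb$i; j <- sb$j; b <- sb$ref_j
      rel <- if (sb$same_side) -1L else 1L
      da <- get_dir(a, i); db <- get_dir(j, b)
      if (da != 0L && db == 0L) {
        set_dir(j, b, rel * da); progressed <- TRUE
      } else if (da == 0L && db != 0L) {
        set_dir(a, i, rel * db); progressed <- TRUE
      } else if (da == 0L && db == 0L) {
        unresolved <- TRUE
      } else if (db != rel * da) {
        warning("inconsistent cis/trans constraints; dropping one descriptor")
      }
    }
    if (!unresolved) break
    if (!progressed) {
      # seed the first unassigned constraint and propagate again
      for (sb in sbs) {
        if (get_dir(sb$ref_i, sb$i) == 0L && get_dir(sb$j, sb$ref_j) == 0L) {
          set_dir(sb$ref_i, sb$i, 1L)
          break
        }
      }
    }
  }

  adj <- adjusted_valency(g$atoms$element, g$atoms$charge, g$valency)

  atom_token <- function(v, out_nbrs) {
    a <- g$atoms[v, ]
    sym <- a$element
    if (a$aromatic) sym <- tolower(sym)
    chi <- ""
    if (stereo_atom_of[v] > 0L) {
      sd <- g$stereo_atoms[[stereo_atom_of[v]]]
      p <- match(sd$nbrs, out_nbrs)
      if (anyNA(p)) stop("stereo neighbour mismatch at atom ", v)
      par <- sd$parity * perm_sign(p)
      chi <- if (par == 1L) "@" else "@@"
    }
    bsum <- 0
    for (u in nb[[v]]) bsum <- bsum + border(v, u)
    himp <- max(0L, adj[v] - as.integer(ceiling(bsum)))
    bare <- a$element %in% organic_subset() && a$charge == 0L &&
      chi == "" && a$h == himp && is.na(a$isotope)
    if (bare) return(sym)
    hs <- if (a$h == 0L) "" else if (a$h == 1L) "H" else paste0("H", a$h)
    cs <- if (a$charge == 0L) ""
          else if (a$charge == 1L) "+"
          else if (a$charge == -1L) "-"
          else if (a$charge > 0L) paste0("+", a$charge)
          else paste0("-", -a$charge)
    is <- if (is.na(a$isotope)) "" else as.character(a$isotope)
    paste0("[", is, sym, chi, hs, cs, "]")
  }

  bond_token <- function(u, v) {
    o <- border(u, v)
    if (o == 2) return("=")
    if (o == 3) return("#")
    if (o == 1.5) {
      if (g$atoms$aromatic[u] && g$atoms$aromatic[v]) return("")
      return(":")
    }
    d <- get_dir(u, v)  # direction u -> v
    if (d == 1L) return("/")
    if (d == -1L) return("\\")
    if (g$atoms$aromatic[u] && g$atoms$aromatic[v]) return("-")
    ""
  }

  emit <- function(v) {
    out_nbrs <- integer(0)
    if (parent[v] > 0L) out_nbrs <- parent[v]
    if (stereo_atom_of[v] > 0L && g$atoms$h[v] == 1L)
      out_nbrs <- c(out_nbrs, 0L)
    rn <- ring_nbrs(v)
    out_nbrs <- c(out_nbrs, rn, children[[v]])
    s <- atom_token(v, out_nbrs)
    for (x in ring_close[[v]][order(vapply(ring_close[[v]],
                                           function(x) x$digit, integer(1)))]) {
      s <- paste0(s, if (x$digit > 9L) paste0("%", x$digit) else x$digit)
    }
    for (x in ring_open[[v]]) {
      bt <- bond_token(v, x$other)
      s <- paste0(s, bt, if (x$digit > 9L) paste0("%", x$digit) else x$digit)
    }
    kids <- children[[v]]
    if (length(kids) > 0L) {
      for (kk in seq_along(kids)) {
        u <- kids[kk]
        part <- paste0(bond_token(v, u), emit(u))
        s <- if (kk < length(kids)) paste0(s, "(", part, ")")
             else paste0(s, part)
      }
    }
    s
  }

  emit(root)
}
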