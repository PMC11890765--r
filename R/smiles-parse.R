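# SMILES reader producing `chemgraph` objects.
#
# Supported grammar: organic-subset bare atoms (B C N O P S F Cl Br I and
# aromatic b c n o p s), bracket atoms with isotope / chirality (@, @@) /
# H-count / charge / atom class, bond symbols - = # : / \, branches, and
# ring-closure digits (including %nn). Disconnected inputs ('.') are
# rejected by contract. Wildcards, quadruple bonds and extended chirality
# (@TB/@SP/...) are not supported.

.bare_aromatic <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a chemical graph
#'
#' @param smiles single SMILES string.
#' @param valency named valency table (see [default_valency()]); used for
#'   implicit-hydrogen assignment and valency validation.
#' @param validate check the valency invariant for every heavy atom.
#' @return a `chemgraph` object: list with `atoms` (element, charge, h,
#'   aromatic, isotope), `bonds` (i, j, order with aromatic = 1.5),
#'   `stereo_atoms` (tetrahedral descriptors) and `stereo_bonds`
#'   (cis/trans descriptors).
#' @export
parse_smiles <- function(smiles, valency = default_valency(),
                         validate = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("SMILES must be a single non-empty string")
  if (grepl(".", smiles, fixed = TRUE))
    stop("disconnected SMILES (containing '.') are rejected: ", smiles)

  ch <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  nch <- length(ch)

  el <- character(); chg <- integer(); hx <- integer(); arom <- logical()
  iso <- integer(); chir <- integer(); brk <- logical(); hadfrom <- logical()
  nbrs <- list()
  bi <- integer(); bj <- integer(); bo <- numeric(); bdir <- integer()
  ring <- list()
  prev <- 0L
  stack <- integer()
  pend_o <- NA_real_
  pend_d <- 0L
  pos <- 1L

  bail <- function(msg) stop("SMILES parse error at position ", pos, " in '",
                             smiles, "': ", msg, call. = FALSE)

  new_atom <- function(sym, aromatic, bracket, isotope = NA_integer_,
                       charge = 0L, hcount = NA_integer_, chirality = 0L) {
    el[[length(el) + 1L]] <<- sym
    chg[[length(chg) + 1L]] <<- charge
    hx[[length(hx) + 1L]] <<- hcount
    arom[[length(arom) + 1L]] <<- aromatic
    iso[[length(iso) + 1L]] <<- isotope
    chir[[length(chir) + 1L]] <<- chirality
    brk[[length(brk) + 1L]] <<- bracket
    hadfrom[[length(hadfrom) + 1L]] <<- FALSE
    nbrs[[length(nbrs) + 1L]] <<- integer()
    a <- length(el)
    if (prev > 0L) {
      o <- pend_o
      if (is.na(o)) o <- if (arom[[prev]] && aromatic) 1.5 else 1
      add_bond(prev, a, o, pend_d)
      hadfrom[[a]] <<- TRUE
    }
    pend_o <<- NA_real_; pend_d <<- 0L
    prev <<- a
    a
  }

  add_bond <- function(a, b, order, dir) {
    bi[[length(bi) + 1L]] <<- a
    bj[[length(bj) + 1L]] <<- b
    bo[[length(bo) + 1L]] <<- order
    bdir[[length(bdir) + 1L]] <<- dir
    nbrs[[a]] <<- c(nbrs[[a]], b)
    nbrs[[b]] <<- c(nbrs[[b]], a)
  }

  ring_digit <- function(d) {
    key <- as.character(d)
    if (is.null(ring[[key]])) {
      # opening: reserve the neighbour slot with a negative placeholder
      nbrs[[prev]] <<- c(nbrs[[prev]], -d - 1000L)
      ring[[key]] <<- list(atom = prev, order = pend_o, dir = pend_d)
    } else {
      op <- ring[[key]]
      ring[[key]] <<- NULL
      if (op$atom == prev) bail("ring bond to self")
      o <- op$order
      if (!is.na(pend_o)) {
        if (!is.na(o) && o != pend_o) bail("ring-closure bond order mismatch")
        o <- pend_o
      }
      if (is.na(o)) o <- if (arom[[op$atom]] && arom[[prev]]) 1.5 else 1
      d2 <- if (pend_d != 0L) -pend_d else op$dir
      # bond registered as op$atom -> prev for direction bookkeeping
      bi[[length(bi) + 1L]] <<- op$atom
      bj[[length(bj) + 1L]] <<- prev
      bo[[length(bo) + 1L]] <<- o
      bdir[[length(bdir) + 1L]] <<- d2
      slot <- which(nbrs[[op$atom]] == -d - 1000L)[1L]
      nbrs[[op$atom]][slot] <<- prev
      nbrs[[prev]] <<- c(nbrs[[prev]], op$atom)
    }
    pend_o <<- NA_real_; pend_d <<- 0L
  }

  while (pos <= nch) {
    c0 <- ch[pos]
    if (c0 == "[") {
      close <- pos
      while (close <= nch && ch[close] != "]") close <- close + 1L
      if (close > nch) bail("unterminated bracket atom")
      body <- paste0(ch[(pos + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|b|c|n|o|p|s|se|as)(@{1,2})?(H[0-9]*)?([+-]+[0-9]*|[+-][0-9]+)?(:[0-9]+)?$",
        body))[[1L]]
      if (length(m) == 0L) bail(paste0("cannot parse bracket atom [", body, "]"))
      isotope <- if (nzchar(m[2L])) as.integer(m[2L]) else NA_integer_
      sym <- m[3L]
      aromatic <- sym %in% c(.bare_aromatic, "se", "as")
      if (aromatic) sym <- paste0(toupper(substr(sym, 1L, 1L)),
                                  substring(sym, 2L))
      chirality <- c(0L, 1L, 2L)[nchar(m[4L]) + 1L]
      hcount <- if (!nzchar(m[5L])) 0L
                else if (m[5L] == "H") 1L
                else as.integer(substring(m[5L], 2L))
      charge <- 0L
      if (nzchar(m[6L])) {
        cs <- m[6L]
        if (grepl("^[+-]+$", cs)) {
          charge <- (nchar(cs)) * (if (substr(cs, 1L, 1L) == "+") 1L else -1L)
        } else {
          sign <- if (substr(cs, 1L, 1L) == "+") 1L else -1L
          charge <- sign * as.integer(gsub("[+-]", "", cs))
        }
      }
      new_atom(sym, aromatic, TRUE, isotope, charge, hcount, chirality)
      pos <- close + 1L
    } else if (c0 %in% c("C", "B") && pos < nch && ch[pos + 1L] %in% c("l", "r") &&
               paste0(c0, ch[pos + 1L]) %in% c("Cl", "Br")) {
      new_atom(paste0(c0, ch[pos + 1L]), FALSE, FALSE)
      pos <- pos + 2L
    } else if (c0 %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      new_atom(c0, FALSE, FALSE)
      pos <- pos + 1L
    } else if (c0 %in% .bare_aromatic) {
      new_atom(toupper(c0), TRUE, FALSE)
      pos <- pos + 1L
    } else if (c0 == "-") {
      pend_o <- 1; pos <- pos + 1L
    } else if (c0 == "=") {
      pend_o <- 2; pos <- pos + 1L
    } else if (c0 == "#") {
      pend_o <- 3; pos <- pos + 1L
    } else if (c0 == ":") {
      pend_o <- 1.5; pos <- pos + 1L
    } else if (c0 == "/") {
      pend_o <- 1; pend_d <- 1L; pos <- pos + 1L
    } else if (c0 == "\\") {
      pend_o <- 1; pend_d <- -1L; pos <- pos + 1L
    } else if (c0 == "(") {
      if (prev == 0L) bail("branch before any atom")
      stack <- c(stack, prev)
      pos <- pos + 1L
    } else if (c0 == ")") {
      if (length(stack) == 0L) bail("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (grepl("[0-9]", c0)) {
      if (prev == 0L) bail("ring digit before any atom")
      ring_digit(as.integer(c0))
      pos <- pos + 1L
    } else if (c0 == "%") {
      if (pos + 2L > nch) bail("truncated %nn ring digit")
      ring_digit(as.integer(paste0(ch[pos + 1L], ch[pos + 2L])))
      pos <- pos + 3L
    } else {
      bail(paste0("unexpected character '", c0, "'"))
    }
  }

  if (length(stack) > 0L) bail("unclosed branch")
  if (length(ring) > 0L) bail("unclosed ring bond(s)")
  if (length(el) == 0L) bail("no atoms")

  n <- length(el)
  atoms <- data.frame(element = el, charge = chg, h = hx, aromatic = arom,
                      isotope = iso, stringsAsFactors = FALSE)
  bonds <- if (length(bi) > 0L)
    data.frame(i = bi, j = bj, order = bo)
  else data.frame(i = integer(), j = integer(), order = numeric())

  # implicit hydrogens for bare (non-bracket) atoms
  bsum <- numeric(n)
  for (k in seq_len(length(bi))) {
    bsum[bi[k]] <- bsum[bi[k]] + bo[k]
    bsum[bj[k]] <- bsum[bj[k]] + bo[k]
  }
  adj <- adjusted_valency(atoms$element, atoms$charge, valency)
  bare <- !brk
  atoms$h[bare] <- pmax(0L, adj[bare] - as.integer(ceiling(bsum[bare])))
  atoms$h[is.na(atoms$h)] <- 0L

  if (validate) {
    over <- ceiling(bsum) + atoms$h > adj
    if (any(over))
      stop("valency exceeded for atom(s) ",
           paste(which(over), collapse = ", "), " in '", smiles, "'")
  }

  # tetrahedral stereo descriptors
  stereo_atoms <- list()
  for (a in which(chir > 0L)) {
    nb <- nbrs[[a]]
    if (atoms$h[a] == 1L) {
      at <- if (hadfrom[a]) 2L else 1L
      nb <- append(nb, 0L, after = at - 1L)
    }
    if (length(nb) != 4L)
      stop("chiral atom ", a, " does not have four substituents in '",
           smiles, "'")
    stereo_atoms[[length(stereo_atoms) + 1L]] <-
      list(atom = a, nbrs = nb, parity = if (chir[a] == 1L) 1L else -1L)
  }

  # cis/trans descriptors from directional bonds
  dirmat <- if (length(bi) > 0L)
    data.frame(i = bi, j = bj, dir = bdir)
  else data.frame(i = integer(), j = integer(), dir = integer())
  dir_of <- function(u, v) {
    # direction of bond u-v as d(u -> v); 0 if bond absent or undirected
    k <- which((dirmat$i == u & dirmat$j == v))
    if (length(k) > 0L) return(dirmat$dir[k[1L]])
    k <- which((dirmat$i == v & dirmat$j == u))
    if (length(k) > 0L) return(-dirmat$dir[k[1L]])
    0L
  }
  stereo_bonds <- list()
  for (k in which(bo == 2)) {
    i0 <- bi[k]; j0 <- bj[k]
    cand_i <- setdiff(nbrs[[i0]], j0)
    cand_j <- setdiff(nbrs[[j0]], i0)
    di <- vapply(cand_i, function(a) dir_of(a, i0), integer(1))
    dj <- vapply(cand_j, function(b) dir_of(j0, b), integer(1))
    if (any(di != 0L) && any(dj != 0L)) {
      a <- cand_i[which(di != 0L)[1L]]
      b <- cand_j[which(dj != 0L)[1L]]
      same <- di[which(di != 0L)[1L]] != dj[which(dj != 0L)[1L]]
      stereo_bonds[[length(stereo_bonds) + 1L]] <-
        list(i = i0, j = j0, ref_i = a, ref_j = b, same_side = same)
    }
  }

  structure(list(atoms = atoms, bonds = bonds,
                 stereo_atoms = stereo_atoms, stereo_bonds = stereo_bonds,
                 valency = valency),
            class = "chemgraph")
}
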