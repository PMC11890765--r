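# XYZ and extended-XYZ readers/writers. Extended XYZ uses the usual
# Properties=species:S:1:pos:R:3[:forces:R:3] comment-line convention
# plus free key=value pairs for per-frame metadata.

#' Write structures to an (extended) XYZ file
#'
#' @param structures list of structure3d (or a single one).
#' @param path output file.
#' @param forces optional list of N x 3 force matrices (adds a forces
#'   column block).
#' @param metadata optional list of per-frame named lists written as
#'   key=value pairs.
#' @export
write_extxyz <- function(structures, path, forces = NULL, metadata = NULL) {
  if (inherits(structures, "structure3d")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(structures)) {
    s <- structures[[fi]]
    n <- length(s$numbers)
    writeLines(as.character(n), con)
    props <- if (is.null(forces)) "Properties=species:S:1:pos:R:3"
             else "Properties=species:S:1:pos:R:3:forces:R:3"
    meta <- c(sprintf("charge=%d", s$charge),
              sprintf("multiplicity=%d", s$multiplicity))
    if (!is.null(metadata) && !is.null(metadata[[fi]])) {
      md <- metadata[[fi]]
      meta <- c(meta, vapply(names(md), function(k) {
        v <- md[[k]]
        if (is.numeric(v)) sprintf("%s=%.12g", k, v)
        else sprintf("%s=%s", k, as.character(v))
      }, character(1)))
    }
    writeLines(paste(c(props, meta), collapse = " "), con)
    el <- element_symbol(s$numbers)
    for (a in seq_len(n)) {
      row <- sprintf("%-3s %18.10f %18.10f %18.10f", el[a],
                     s$positions[a, 1L], s$positions[a, 2L],
                     s$positions[a, 3L])
      if (!is.null(forces)) {
        f <- forces[[fi]]
        row <- paste0(row, sprintf(" %18.10f %18.10f %18.10f",
                                   f[a, 1L], f[a, 2L], f[a, 3L]))
      }
      writeLines(row, con)
    }
  }
  invisible(path)
}

#' Read an (extended) XYZ file
#'
#' @param path file path.
#' @return list of frames; each a list with `structure` (structure3d),
#'   `forces` (N x 3 or NULL) and `metadata` (named character list).
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    comment <- lines[i + 1L]
    toks <- regmatches(comment,
                       gregexpr('[A-Za-z_][A-Za-z0-9_]*="[^"]*"|[A-Za-z_][A-Za-z0-9_]*=[^ ]+',
                                comment))[[1L]]
    meta <- list()
    for (t in toks) {
      key <- sub("=.*$", "", t)
      val <- sub("^[^=]*=", "", t)
      meta[[key]] <- gsub('^"|"$', "", val)
    }
    has_forces <- grepl("forces:R:3", comment, fixed = TRUE)
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    el <- vapply(parts, `[[`, character(1), 1L)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frc <- if (has_forces)
      t(vapply(parts, function(p) as.numeric(p[5:7]), numeric(3)))
    else NULL
    chg <- if (!is.null(meta$charge)) as.integer(meta$charge) else 0L
    mult <- if (!is.null(meta$multiplicity)) as.integer(meta$multiplicity)
            else 1L
    frames[[length(frames) + 1L]] <-
      list(structure = structure3d(element_number(el), pos, chg, mult),
           forces = frc,
           metadata = meta[setdiff(names(meta),
                                   c("Properties", "charge", "multiplicity"))])
    i <- i + 2L + n
  }
  frames
}
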