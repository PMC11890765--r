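# Hierarchical record store: graph -> conformation -> calculation, with
# stable 128-bit keys, JSONL export/import, and referential-integrity
# audit. Storage is JSON-lines per record type (human-diffable and
# streaming-friendly); field names on export follow the common dataset
# conventions (energy in Hartree, forces in Hartree/Bohr, positions in
# Bohr), while everything in memory stays in eV / Angstrom.

# 128-bit hex key; MD5 of the text (no SHA-256 implementation is
# available in the supported dependency set; same 128-bit contract)
record_key <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Create an empty record store
#' @return environment-backed store of class `forge_store`.
#' @export
forge_store <- function() {
  st <- new.env(parent = emptyenv())
  st$graphs <- list()
  st$conformations <- list()
  st$calculations <- list()
  st$log <- list()
  class(st) <- "forge_store"
  st
}

#' @export
print.forge_store <- function(x, ...) {
  cat("<forge_store> ", length(x$graphs), " graphs, ",
      length(x$conformations), " conformations, ",
      length(x$calculations), " calculations\n", sep = "")
  invisible(x)
}

.stable_digest <- function(obj) {
  record_key(paste(utils::capture.output(utils::str(obj, digits.d = 12)),
                   collapse = "\n"))
}

#' Insert a graph record
#'
#' Idempotent on canonical SMILES: duplicates collapse onto one record.
#'
#' @param store forge_store.
#' @param smiles canonical SMILES.
#' @param provenance character tag (source / generator chain).
#' @return the record key (invisibly the whole record as attribute).
#' @export
put_graph <- function(store, smiles, provenance = "import") {
  key <- record_key(smiles)
  existing <- store$graphs[[key]]
  if (!is.null(existing)) {
    if (!identical(existing$canonical_smiles, smiles))
      stop("key collision with differing payload for ", smiles)
    return(key)
  }
  store$graphs[[key]] <- list(
    key = key, canonical_smiles = smiles,
    heavy_atom_count = heavy_atom_count(smiles),
    provenance = provenance)
  key
}

#' Insert a conformation record
#'
#' @param store forge_store.
#' @param graph_key parent graph key (must exist).
#' @param s structure3d.
#' @param kind "conformer" or "offequilibrium".
#' @param draw optional sample-draw provenance list.
#' @return record key.
#' @export
put_conformation <- function(store, graph_key, s,
                             kind = c("conformer", "offequilibrium"),
                             draw = NULL) {
  kind <- match.arg(kind)
  if (is.null(store$graphs[[graph_key]]))
    stop("orphan insert: graph key ", graph_key, " not in store")
  key <- record_key(paste(graph_key,
                          paste(sprintf("%.9f", s$positions), collapse = ","),
                          sep = "|"))
  if (!is.null(store$conformations[[key]])) return(key)
  store$conformations[[key]] <- list(
    key = key, graph_key = graph_key,
    atomic_numbers = s$numbers, positions = s$positions,
    charge = s$charge, multiplicity = s$multiplicity,
    kind = kind, draw = draw)
  key
}

#' Insert a calculation record
#'
#' @param store forge_store.
#' @param conformation_key parent conformation key (must exist).
#' @param calculator calculator name.
#' @param result list: energy, forces, optional bond_orders, charges,
#'   formation_energy, flags.
#' @return record key.
#' @export
put_calculation <- function(store, conformation_key, calculator, result) {
  if (is.null(store$conformations[[conformation_key]]))
    stop("orphan insert: conformation key ", conformation_key,
         " not in store")
  key <- record_key(paste(conformation_key, calculator, sep = "|"))
  if (!is.null(store$calculations[[key]])) return(key)
  store$calculations[[key]] <- c(
    list(key = key, conformation_key = conformation_key,
         calculator = calculator),
    result)
  key
}

#' Children of a record
#'
#' @param store forge_store.
#' @param key a graph or conformation key.
#' @return list of child records (conformations of a graph, calculations
#'   of a conformation).
#' @export
children <- function(store, key) {
  if (!is.null(store$graphs[[key]]))
    return(Filter(function(r) r$graph_key == key, store$conformations))
  if (!is.null(store$conformations[[key]]))
    return(Filter(function(r) r$conformation_key == key,
                  store$calculations))
  stop("key not found: ", key)
}

#' Audit referential integrity
#'
#' @param store forge_store.
#' @return TRUE invisibly; errors on the first orphan found.
#' @export
audit_store <- function(store) {
  for (r in store$conformations)
    if (is.null(store$graphs[[r$graph_key]]))
      stop("conformation ", r$key, " has dangling graph key")
  for (r in store$calculations)
    if (is.null(store$conformations[[r$conformation_key]]))
      stop("calculation ", r$key, " has dangling conformation key")
  invisible(TRUE)
}

# --- JSONL export / import ---------------------------------------------------

.to_export_units <- function(rec) {
  hc <- forge_constants
  if (!is.null(rec$positions))
    rec$positions <- rec$positions / hc$bohr_A            # A -> Bohr
  if (!is.null(rec$energy)) rec$energy <- rec$energy / hc$hartree_eV
  if (!is.null(rec$formation_energy))
    rec$formation_energy <- rec$formation_energy / hc$hartree_eV
  if (!is.null(rec$forces))
    rec$forces <- rec$forces * (hc$bohr_A / hc$hartree_eV) # eV/A -> Eh/a0
  rec
}

.from_export_units <- function(rec) {
  hc <- forge_constants
  if (!is.null(rec$positions))
    rec$positions <- rec$positions * hc$bohr_A
  if (!is.null(rec$energy)) rec$energy <- rec$energy * hc$hartree_eV
  if (!is.null(rec$formation_energy))
    rec$formation_energy <- rec$formation_energy * hc$hartree_eV
  if (!is.null(rec$forces))
    rec$forces <- rec$forces / (hc$bohr_A / hc$hartree_eV)
  rec
}

.write_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    r$key_hash <- record_key(r$key)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Export a store as JSON-lines shards
#'
#' Writes graphs.jsonl, conformations.jsonl and calculations.jsonl into
#' `dir`. Positions are exported in Bohr, energies in Hartree, forces in
#' Hartree/Bohr; each line carries a `key_hash` field.
#'
#' @param store forge_store.
#' @param dir output directory (created if needed).
#' @return dir, invisibly.
#' @export
export_jsonl <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_jsonl(store$graphs, file.path(dir, "graphs.jsonl"))
  .write_jsonl(lapply(store$conformations, .to_export_units),
               file.path(dir, "conformations.jsonl"))
  .write_jsonl(lapply(store$calculations, .to_export_units),
               file.path(dir, "calculations.jsonl"))
  invisible(dir)
}

#' Import a store from JSON-lines shards
#' @param dir directory holding the three shards.
#' @return forge_store.
#' @export
import_jsonl <- function(dir) {
  store <- forge_store()
  rd <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) return(list())
    lines <- readLines(path, warn = FALSE)
    out <- lapply(lines, function(l)
      jsonlite::fromJSON(l, simplifyVector = TRUE))
    names(out) <- vapply(out, `[[`, character(1), "key")
    out
  }
  store$graphs <- rd("graphs.jsonl")
  store$conformations <- lapply(rd("conformations.jsonl"), function(r) {
    r <- .from_export_units(r)
    r$positions <- matrix(as.numeric(r$positions), ncol = 3L)
    r
  })
  store$calculations <- lapply(rd("calculations.jsonl"), function(r) {
    r <- .from_export_units(r)
    if (!is.null(r$forces))
      r$forces <- matrix(as.numeric(r$forces), ncol = 3L)
    if (!is.null(r$bond_orders))
      r$bond_orders <- matrix(as.numeric(r$bond_orders),
                              nrow = sqrt(length(r$bond_orders)))
    r
  })
  audit_store(store)
  store
}
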