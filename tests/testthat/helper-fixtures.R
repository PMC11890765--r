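# Shared fixtures. Everything is generated in code; expensive objects are
# memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  hit <- .fixture_cache[[name]]
  if (!is.null(hit)) return(hit)
  val <- build()
  .fixture_cache[[name]] <- val
  val
}

# optimized conformer of a small molecule on the toy force field
opt_conformer <- function(smiles, seed = 2L, polish = FALSE) {
  fixture(paste0("opt_", smiles, "_", seed, "_", polish), function() {
    g <- parse_smiles(smiles)
    ff <- toy_forcefield(g)
    c0 <- local_optimize(embed_initial(g, seed = seed), ff, pre_opt = TRUE)
    if (polish) c0 <- local_optimize(c0$structure, ff, f_max = 1e-6)
    list(graph = g, ff = ff, conf = c0)
  })
}

# a rigid random rotation + translation applied to coordinates
random_pose <- function(x, seed = 1L) {
  set.seed(seed)
  th <- stats::runif(3L, 0, 2 * pi)
  Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0,
                 sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                 0, sin(th[2]), cos(th[2])), 3, 3, byrow = TRUE)
  x %*% (Rz %*% Rx) + matrix(stats::runif(3L, -2, 2), nrow(x), 3L,
                             byrow = TRUE)
}

# batch canonicalization through RDKit (pre-installed python), used only
# as an independent oracle for molecule identity
rdkit_canonical <- function(smiles) {
  fin <- tempfile(); fout <- tempfile()
  writeLines(smiles, fin)
  code <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    sprintf("inp = open('%s').read().splitlines()", fin),
    "out = []",
    "for s in inp:",
    "    m = Chem.MolFromSmiles(s)",
    "    out.append(Chem.MolToSmiles(m) if m is not None else 'PARSE_FAIL')",
    sprintf("open('%s','w').write('\\n'.join(out) + '\\n')", fout),
    sep = "\n")
  res <- system2("python", c("-c", shQuote(code)), stdout = TRUE,
                 stderr = TRUE)
  if (!file.exists(fout)) stop("RDKit oracle failed: ",
                               paste(res, collapse = " "))
  readLines(fout)
}

# alternative valid SMILES spellings of the same molecule: rewrite from a
# random traversal order
respell <- function(smiles, seed = 1L) {
  g <- parse_smiles(smiles)
  set.seed(seed)
  write_smiles(g, ranks = sample(nrow(g$atoms)))
}
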