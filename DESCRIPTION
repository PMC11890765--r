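Package: molforge
Title: Systematic Generation of Small-Molecule Training Structures
Version: 0.1.0
Authors@R:
    person("Forge", "Maintainers", email = "maintainers@molforge.dev",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for constructing quantum-chemistry
    training data: systematic enumeration of small chemical graphs under
    valency constraints, chemical enrichment (protonation states,
    stereoisomers, amon subgraphs, tripeptides with disulfide variants),
    conformer search with symmetry-aware deduplication, normal-mode
    sampling of off-equilibrium 3D structures, and automated quality and
    outlier filters. Quantum-chemistry engines are abstracted behind a
    pluggable calculator contract; a built-in analytic toy force field
    makes the whole pipeline runnable and testable without external codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
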