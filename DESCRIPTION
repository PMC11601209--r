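Package: plgicomp
Title: Equilibrium Competition-Binding Models and Indel Profiling for
    Pentameric Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing the function of electrically silent pentameric
    ligand-gated ion channels (pLGICs) with equilibrium ligand-binding
    competition assays. Implements a two-conformation allosteric receptor
    model with identical, independent orthosteric and allosteric sites;
    exact equilibrium occupancies and an exhaustive microstate oracle;
    simulation of labeled-toxin competition curves with optional allosteric
    modulators and ligand-depletion correction; global weighted Hill fitting
    of replicate curves with component selection and fold-shift error
    propagation; a seeded synthetic-assay generator with counting noise; and
    a reference-anchored insertion/deletion frequency analysis of multiple
    sequence alignments, including detection of indel-free stretches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    seqinr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
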