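Package: tcellkpr
Title: Phenotypic Models of T-Cell Activation by Kinetic Proofreading
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Comparative analysis of nine phenotypic mass-action models of
    T-cell receptor (TCR) activation by peptide-MHC ligands: the occupancy
    model, kinetic proofreading (KPR), and KPR variants with limited
    signalling, sustained signalling, SHP-1 negative feedback, a stabilizing
    activation chain, and incoherent feed-forward output layers. Provides
    literature-derived parameter tables, reaction-network constructors with
    generated mass-action right-hand sides, chemical-reaction-network
    deficiency and weak-reversibility analysis, stiff ODE simulation,
    multistart steady-state location with linear stability classification,
    analytic and numeric dose-response surfaces with E_max and EC_50
    extraction, qualitative feature classification (optima, bimodality,
    curve crossings), and Latin-hypercube/partial-rank-correlation
    sensitivity analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
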