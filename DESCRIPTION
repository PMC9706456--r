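Package: healthnet
Title: Cross-Species Co-Expression Meta-Analysis of Health-Associated Gene Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a cross-species meta-study of health(span) based on
    weighted gene co-expression network analysis. For each expression
    experiment the package derives a per-sample health phenotype score from
    a declarative scorecard, builds an unsigned weighted co-expression
    network with automated scale-free soft-threshold selection, computes
    topological overlap, detects modules, and retains modules whose
    eigengene correlates with the health score. Hub genes (soft
    connectivity) and module-membership genes (kME) are mapped to human
    orthologs and intersected across species to produce consensus gene
    tables, a consensus interaction graph with spanning-tree
    simplification, and permutation-based significance estimates. A
    synthetic-data generator with planted, health-correlated modules
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
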