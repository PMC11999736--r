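Package: selexdyn
Title: Enrichment Dynamics and Structure Combinatorics for In Vitro
    Selection of Ribozymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models of in vitro selection (SELEX) of catalytic
    RNA from random-sequence libraries. Provides closed-form enrichment
    factors for catalysts, background sequences and separation artefacts;
    binomial survival models for rare functional sequences in the first
    selection round; deterministic multi-round frequency recursions with
    stringency (reaction-time) schedules and cofactor counter-selection;
    combinatorics of sequences matching a ribozyme secondary-structure
    constraint exactly or within a few mutations, across all placements of
    its modules in a randomized region; and a multi-cluster model of
    selection with beneficial mutations that reproduces the weak correlation
    between cluster frequency and fitness seen in sequencing data. Results
    are returned as tibbles and plot with 'ggplot2'.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
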