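Package: upstreamkit
Title: Upstream Regulatory Analysis from Differential Expression to Master Regulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an open, testable "upstream analysis" pipeline for
    two-group expression studies: empirical-Bayes moderated differential
    expression, MATCH-style position-weight-matrix scanning of promoter
    sequences, yes/no binomial enrichment of transcription-factor binding
    sites, genetic-algorithm discovery of composite regulatory modules, and
    graph search for master regulators upstream of the module transcription
    factors with positive-feedback-loop detection and a three-component
    ranking. Ships a synthetic-data generator with a planted-truth manifest
    so every stage and the end-to-end run are verifiable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    igraph,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
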