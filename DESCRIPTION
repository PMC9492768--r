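Package: boolcell
Title: Boolean Network Rule Inference and Pathway Analysis for Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers executable Boolean rule sets for signed prior-knowledge
    signaling networks from binarized single-cell RNA-seq data using a genetic
    algorithm followed by a node-wise local search, quantifies per-gene
    influence by in-silico knock-in/knock-out perturbation of the learned
    models, scores pathway dysregulation between two cell groups with a
    permutation test, and maps individual cells to attractor signaling states
    by Hamming distance. Includes a synthetic-data generator that samples
    cells from the attractor states of known Boolean networks so every stage
    of the pipeline can be validated without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    rlang,
    xml2,
    igraph,
    Matrix,
    jsonlite,
    withr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
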