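Package: ncfga
Title: Boolean Gene Regulatory Network Inference with a Constrained Genetic Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Infers both the structure and the nested-canalyzing Boolean update
    rules of a gene regulatory network from steady-state wild-type and
    perturbation (knockout/overexpression) expression data. Perturbation
    responses are distilled into hard path-consistency constraints (signed
    direct or indirect regulatory paths) and a crossover-free genetic
    algorithm searches constraint-satisfying networks whose synchronous
    attractors best reproduce the observed steady states. Includes a
    Barabasi-Albert benchmark generator with random nested canalyzing rules,
    per-gene 2-means binarization of real-valued expression, structural
    (precision/recall/accuracy over signed edges) and dynamics (attractor
    similarity) scoring, plain-text dataset/network formats and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
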