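Package: connectomlp
Title: Connectome Classification with Multilayer Perceptrons and
    Input-Gradient Saliency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify weighted undirected structural connectomes
    with a small multilayer perceptron and to rank brain regions and
    connections by their contribution to correct classification.
    Connectome matrices built on the 84-region Desikan-Killiany
    parcellation are validated, vectorized over the strict upper
    triangle (3486 edges), and min-max normalized per participant; a
    four-layer perceptron (1024/256/64/2 units) is trained with
    full-batch Adam under repeated-seed stratified 5-fold
    cross-validation; input gradients of the true-class probability,
    collected over correctly predicted held-out participants, are
    averaged into per-class edge gradient scores, summed into node
    strengths, and ranked, including cross-hemisphere edge summaries.
    A synthetic-cohort simulator with planted group effects supports
    end-to-end validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
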