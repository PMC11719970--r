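Package: methylscreen
Title: DNA Methylation Biomarker Screening and Multi-Class Degenerative
    Disease Prediction
Version: 0.1.0
Authors@R:
    person("methylscreen", "developers", email = "methylscreen@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for screening CpG methylation
    biomarkers from Illumina array beta-value matrices and predicting
    degenerative disease classes. Implements a two-stage CpG selection
    procedure (a randomized-tree ensemble importance filter followed by a
    feature-count scan driven by a multi-scale one-dimensional convolutional
    diagnosis model under cross-validation), cosine-similarity KNN graph
    construction with Louvain community detection and a K-stabilization scan,
    a residual multi-class network with global-average-pooling embeddings,
    and per-class mean Shapley feature attribution. Ships a synthetic
    beta-matrix cohort generator so the full pipeline is testable without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
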