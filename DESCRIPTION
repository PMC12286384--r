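Package: sparseae
Title: Sparse-Autoencoder Discovery of Cancer Subtype Marker Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies subtype-discriminative marker genes from non-negative
    expression matrices (FPKM-like) with a shallow autoencoder whose encoder
    weights carry an L2,1 (row-sparsity) penalty, so that the Euclidean norm
    of each encoder row scores the corresponding gene. Marker sets are
    stabilised by a replicate-and-intersect consensus protocol across multiple
    runs and random seeds, validated by class-weighted random-forest
    multiclass classification with one-vs-rest ROC/AUC reporting, and
    organised into functional modules by Markov clustering of a
    confidence-filtered protein-interaction network. Includes a synthetic
    multi-subtype expression generator with planted markers, zero inflation
    and outlier genes, plus a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    pROC,
    ranger,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
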