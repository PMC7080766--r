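Package: repoforest
Title: Drug Repositioning with Kernel Similarity Fusion, Sparse
    Autoencoders and Rotation Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-disease associations for drug repositioning.
    Fuses Gaussian interaction profile kernels computed from a binary
    drug-disease association matrix with cluster-enhanced drug structural
    similarity and MeSH-derived disease semantic similarity, learns a
    compact representation of each drug-disease pair with a sparse
    autoencoder followed by principal component analysis, and scores
    pairs with a rotation-forest ensemble of decision trees. Includes
    stratified k-fold cross-validation with leakage-safe per-fold
    similarity recomputation, ROC/AUC evaluation, a disease-masking
    ranking mode for case studies, and a synthetic block-model data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
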