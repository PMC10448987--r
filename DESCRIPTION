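Package: beene
Title: Batch Effect Estimation in RNA-Seq Data Using Guided Nonlinear Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies batch effects in bulk and single-cell
    RNA-seq expression data. A guided autoencoder embeds cells into a
    low-dimensional latent space while auxiliary prediction heads retain
    batch-specific and biological variation, making nonlinear batch effects
    visible to local mixing metrics. Implements the kBET chi-squared
    rejection-rate test and the local inverse Simpson's index (iLISI) on any
    embedding, a PCA baseline, a gamma-Poisson single-cell count simulator
    with controllable linear and nonlinear additive batch effects, and an
    end-to-end estimation pipeline with cross-validation and parameter
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
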