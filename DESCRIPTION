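Package: scdrp
Title: Bulk-to-Single-Cell Transfer Learning for Drug-Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug response (sensitive vs resistant) for individual
    cells by transferring a predictor trained on labelled bulk expression
    profiles to single-cell RNA-seq data. Denoising autoencoders embed both
    domains; a multi-head self-attention predictor scores drug sensitivity;
    joint training aligns the two latent spaces with a maximum mean
    discrepancy penalty and a Louvain-cluster coherence regularizer.
    Includes quality-control filtering, UMI normalization, class balancing
    (SMOTE / oversampling), evaluation metrics (precision, recall, F1,
    AUC-ROC, average precision), integrated-gradients key-gene attribution,
    gene-set scoring with a random-gene-set null test, and a synthetic
    paired bulk/single-cell data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
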