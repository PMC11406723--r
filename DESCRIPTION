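Package: scHiCtype
Title: Cell-Type Classification from Single-Cell Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts single-cell Hi-C read pairs into per-cell embeddings and
    predicts cell types with a small feed-forward neural network. The pipeline
    bins intra-chromosomal read pairs into per-chromosome contact matrices,
    applies cell-level quality control, densifies each matrix by mean-filter
    convolution followed by random walk with restart, embeds cells by
    per-chromosome PCA plus a final PCA, and trains a two-hidden-layer
    multilayer perceptron with dropout. Includes clustering-agreement and
    classification metrics (adjusted Rand index, normalized mutual
    information, ROC/AUC, accuracy, k-fold cross-validation) and a seeded
    synthetic single-cell Hi-C data generator for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
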