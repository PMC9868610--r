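Package: slview
Title: Multi-View Graph Convolutional Prediction of Cell-Specific
    Synthetic Lethality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cancer cell-specific synthetic-lethal (SL) gene pairs
    by encoding five biological networks (a cell-specific SL graph, physical
    and genetic protein-interaction networks, and co-expression and
    co-essentiality networks) with weight-shared two-layer graph
    convolutions, integrating the per-view gene embeddings by element-wise
    max pooling, and classifying gene pairs with a small feed-forward head
    trained under balanced negative sampling. Ships readers for plain-text
    edge lists, genetic-interaction score tables and omics matrices,
    leave-gene-combination-out and leave-gene-out evaluation splits, ranking
    metrics (ROC-AUC, AUPR, Precision at k percent, F-max), and a synthetic
    data generator that plants a latent-factor SL signal so the whole
    pipeline is exercisable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
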