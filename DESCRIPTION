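Package: generisk
Title: Gene Network Node Classification for Disease Risk Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds labeled, featurized gene interaction graphs from
    SFARI-style gene tables and protein interaction network (PIN) edge lists,
    balances severe class imbalance by graph-aware node duplication, and
    trains and evaluates four node classifiers (graph convolutional network,
    GraphSAGE, an all-pair/kernelized-attention graph transformer, and a
    multilayer perceptron baseline) on binary risk, multi-class risk, and
    syndromic gene classification tasks. Includes a synthetic cohort
    generator with planted class sizes, edge homophily, and chromosome-band
    signal so the full pipeline can be exercised and validated without any
    external download, plus per-class specificity/sensitivity, accuracy, F1,
    ROC with Youden-optimal thresholds, t-SNE embedding projections, and
    top-confidence gene rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
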