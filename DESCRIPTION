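Package: ddapre
Title: Drug-Disease Association Prediction with Similarity Undersampling
    and Stacked Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tidyverse-style toolkit for predicting drug-disease
    associations from molecular structure and disease ontology position.
    Drugs are embedded by a Morgan-substructure sentence model trained
    with skip-gram (mol2vec-style, optionally fused with an external
    embedding table); diseases are embedded by uniform random walks over
    the MeSH TreeNumber ancestor DAG fed to the same skip-gram trainer
    (DeepWalk-style). Class imbalance in the pair space is handled by
    K-means similarity undersampling with an adaptive choice among five
    distance metrics and drug-grouped quotas; features are ranked by the
    one-way ANOVA F statistic; prediction uses a two-layer stacking
    ensemble (gradient-boosted trees, CART, random forest, and a
    training-free one-shot classifier under a logistic meta-model), with
    rank-based AUC / trapezoidal AUPR evaluation and LIME-style local
    surrogate explanations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    xgboost,
    ranger,
    rpart,
    glmnet,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml
Config/testthat/edition: 3
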