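Package: msmeal
Title: Multivariate Smooth Mapping and Extreme Active Learning for
    Visible-NIR Reflectance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification of plant species from visible-near-infrared
    reflectance spectra under tight labeling budgets. Provides a global
    spectral reconstruction stage (multiplicative scatter correction,
    weighted moving-window smoothing, and Isomap geodesic embedding with
    RMSE-based component selection), a second-order gradient-boosted-tree
    classifier with softmax multiclass output, pool-based active learning
    with uncertainty querying, confusion-matrix evaluation metrics
    (overall accuracy, Cohen's kappa, macro precision/recall/F1), readers
    and writers for spectra CSV and minimal ENVI BIL hyperspectral cubes,
    and a synthetic grass-spectra generator for fully reproducible
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml,
    nnet,
    randomForest,
    rpart
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
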