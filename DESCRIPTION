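Package: kboost
Title: Cluster-Based Undersampling with Boosted Decision Trees for
    Imbalanced Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for two-class imbalanced classification built around a
    K-means, distance-thresholded undersampling scheme: instances lying far
    from their cluster centroid (presumed near the class boundary) are
    selected into a balanced training subset, which is then classified by an
    AdaBoost.M1 ensemble of gain-ratio (C4.5-style) decision trees.  Includes
    random-undersampling and SMOTE baselines, the hybrid RUSBoost and
    SMOTEBoost ensembles, confusion-matrix metrics suited to skewed classes
    (Matthews correlation coefficient, G-mean, AUC), Friedman/Nemenyi
    rank-based method comparison, a synthetic imbalanced-data generator, and
    a cross-validated experiment runner with leakage-free in-fold resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
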