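Package: leakyforest
Title: Encoding-Aware Random Forests and Out-of-Bag Leakage Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Random forest classification for purely categorical predictors
    with explicit control over how levels are ordinal-encoded (target-agnostic
    alphabetical integer encoding, or target-based encodings using two-class
    proportions or the first principal component of the weighted covariance
    matrix of per-level class probabilities) and over when the encoding is
    fitted (once on the full training set before bagging, or independently on
    each bootstrap sample after bagging). Computes out-of-bag error and five
    variable-importance measures (mean decrease in impurity, permutation
    importance, actual impurity reduction, holdout importance, and
    independent-holdout importance), and ships a null-simulation engine that
    quantifies how target-based encoding before bagging leaks response
    information into out-of-bag samples and holdout folds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ranger,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
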