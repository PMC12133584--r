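Package: conncpm
Title: Connectome-Based Predictive Modeling with Lesioning and
    Misclassification Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) of behavioral
    outcomes from functional-connectivity matrices: edge-wise feature
    selection, positive/negative network-strength summary scores, linear
    prediction over repeated train/test splits, permutation-based
    inference, virtual network lesioning for feature importance, a
    misclassification-index framework with covariate dissection and
    covariate-controlled accuracy, an inverted-model experiment for
    systematically mispredicted subjects, and a synthetic
    functional-connectivity generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
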