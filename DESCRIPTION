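Package: rfpt
Title: Random Forests of Perfect Trees for Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grows massive randomized forests of "perfect" decision trees
    whose nodes are neurons: thresholded linear combinations with ternary
    coefficients in {-1, 0, +1}. Trees are induced in a half-Christmas-tree
    architecture that finalizes one prediction class per node and reinjects
    the other into the trunk, and only trees reaching 100% sensitivity and
    specificity on the training observations contribute to feature
    statistics. Each feature is summarized by ten information criteria
    describing its predictive quality, its proximity to the outcome and the
    complexity of its relationship with the outcome, and by a composite
    score used for biomarker selection in high-dimensional binary-outcome
    data such as expression microarrays. Includes a reproducible
    synthetic-data generator with planted feature archetypes and an
    evaluation harness (confusion metrics, repeated stratified
    cross-validation, stepwise AIC ordering curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
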