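Package: editRF
Title: mRMR Feature Selection and Random-Forest Prediction of A-to-I RNA Editing Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts adenosine-to-inosine (A-to-I) RNA editing sites from
    alignment-derived feature tables. Features are ranked by the Maximum
    Relevance Minimum Redundancy (mRMR) criterion computed on three-state
    discretized features via plug-in mutual information; an Incremental
    Feature Selection (IFS) sweep evaluates every top-k feature set by
    seeded stratified 10-fold cross-validation with a random-forest
    classifier, and the optimal set (maximum Matthews correlation
    coefficient) trains the final model. Includes confusion-matrix metrics
    (Sn, Sp, Acc, MCC), a synthetic-data generator with planted
    informative, redundant and noise features, delimited-text I/O for all
    pipeline artifacts, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    randomForest,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
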