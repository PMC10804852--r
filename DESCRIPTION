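Package: elcdr
Title: Separability-Weighted Ensemble Fusion for Crop Leaf Disease Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ensemble learning for multi-class image classifiers that weights
    each member model by the geometry of its training-set feature embedding:
    the ratio of the mean distance between class centroids (bcD) to the mean
    distance of training vectors from their own class centroid (icD). Member
    softmax outputs are fused by these normalized weights; majority voting
    (with invalid-vote handling) and uniform average weighting are included as
    baselines, together with multi-class evaluation metrics (accuracy, macro
    precision/recall/F1, confusion matrix with an invalid-prediction column),
    a seeded synthetic Gaussian feature-space generator so the full pipeline
    is testable without images or trained networks, and delimited-text
    readers/writers plus a subcommand CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
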