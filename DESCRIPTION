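Package: nodulecascade
Title: Multi-Task Coarse-to-Fine Segmentation and Classification of Lung
    Nodule Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-task cascade for pulmonary nodule analysis on 2D CT
    patches: a coarse segmentation network produces a nodule probability
    map that is distilled, as a prior location channel, into a fine
    segmentation network (via a 1x1 fusion layer at the encoder
    bottleneck) and into a benign/malignant classification network (as a
    fourth input channel). Segmentation is trained with a hybrid
    Dice + online hard-pixel rank loss; classification with binary
    cross-entropy. Includes the set-cardinality overlap metrics (Dice,
    Jaccard, pixel accuracy, recall, specificity) and classification
    metrics (accuracy, sensitivity, specificity, AUC), the annotation
    filtering/labelling rules, patch cropping, augmentation and manifest
    splitting, a synthetic patch generator (smooth versus spiculated
    blobs) for desk-scale experiments, class-activation-map
    visualisation, and a compact gradient-checked CNN engine
    (depthwise-separable convolutions, batch normalisation, Adam) that
    all three subnetworks are built on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
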