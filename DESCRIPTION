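Package: latefuse
Title: Gradient-Optimized Late Fusion of Multi-Omic and Histology Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Late-fusion classification of cancer subtypes from heterogeneous
    modalities (gene expression, miRNA expression, copy-number values,
    DNA-methylation beta values, and tiled whole-slide histology images).
    Each modality gets its own probabilistic classifier (RBF-kernel support
    vector machines with grid-search tuning for molecular data; a pluggable
    tile-level classifier with tile-fraction aggregation for slides); class
    probabilities are then combined by a per-class, per-modality weight
    matrix kept row-stochastic by a softmax and learned by minibatch Adam
    under cross-entropy loss. Missing modalities enter the fusion as exact
    zeros, so predictions degrade gracefully with incomplete screening.
    Includes feature screening (t-test with Bonferroni control, fold-change
    and coefficient-of-variation filters, mRMR ranking), stratified
    patient-wise cross-validation, modality-subset sweeps, and a synthetic
    multi-modal cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    nnet,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    png,
    yaml
Config/testthat/edition: 3
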