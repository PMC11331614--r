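Package: hemil
Title: Weakly-Supervised Attention MIL for HER2 Status from H&E Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end weakly-supervised pipeline for predicting
    HER2-negative / HER2-low / HER2-high status from hematoxylin-and-eosin
    whole-slide images. Implements overlapping tile enumeration, Macenko
    stain normalization to a reference image, a three-class
    tumor/non-tumor/background tile filter, per-slide feature-bag
    construction with a pluggable tile encoder, a clustering-constrained
    gated-attention multiple-instance classifier trained with a weighted
    bag cross-entropy plus smooth-SVM instance loss, six IHC/ISH-derived
    training partitions with patient-level stratified cross-validation,
    and attention-based explainability (actionable tiles, attention
    heatmaps, principal-component bin maps). A synthetic-cohort generator
    with planted witness tiles makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    pROC,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
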