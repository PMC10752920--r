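Package: gazeface
Title: Human-Attention-Guided Multi-Scale Face Model and Detector
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a multi-scale face model from Laplacian-of-Gaussian
    scale-space blob features pooled over aligned face images. Per-scale
    kernel density estimates of feature locations yield model points; the
    spatial scales retained by the model are selected by comparing k-means
    clusters of the feature clouds against clusters of human eye-tracking
    fixations. Detection runs a coarse-to-fine cascade of linear SVM
    classifiers over HOG patch descriptors, and detections are scored
    against ground truth with IoU-based precision/recall. Includes a
    seeded synthetic generator for face images, clutter negatives,
    annotated scenes and observer fixation sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    KernSmooth,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils-image.R'
    'scalespace.R'
    'densitymap.R'
    'descriptors.R'
    'scale-selection.R'
    'detector.R'
    'evaluation.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
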