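Package: segrefine
Title: Segmentation Refinement Toolkit for Spatial Transcriptomics Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for refining cell segmentation on spatial transcriptomics
    microscopy images at small annotation budgets: patch cropping with
    reflection padding, semantic-to-instance mask conversion, grouped
    train/validation list construction, instance-level segmentation
    evaluation by IoU matching (precision, recall, F1, Jaccard, Dice),
    six-metric morphological and spatial quantification of label masks,
    aggregation of spot-level gene expression tables into single-cell
    expression matrices, a deterministic synthetic tissue generator for
    dense/low-contrast and sparse/high-contrast regimes, and an iterative
    fine-tuning loop with a pluggable segmenter contract and a classical
    watershed baseline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    tiff,
    png,
    igraph,
    jsonlite,
    EBImage,
    methods,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
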