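Package: cytoscreen
Title: Two-Stage Cytopathology Screening with Nested U-Net Segmentation
    and Contrastive Cell-Clump Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for screening cytopathology image tiles
    for malignant cell clumps. Tiles are filtered by simple intensity
    statistics, segmented by a nested dense-skip U-Net with a channel
    self-attention bottleneck, multi-level semantic supervision and a
    hybrid cross-entropy/Dice loss, post-processed morphologically, and
    the extracted regions of interest are classified as benign or
    malignant by a convolutional encoder trained with a label-supervised
    contrastive loss backed by a momentum encoder and a FIFO labeled
    memory bank. Includes a seeded synthetic cytology-tile generator with
    ground-truth masks in two staining palettes, evaluation metrics
    (Dice, confusion-matrix metrics, ROC/AUC), grouped cross-validation
    and a command-line interface. All network training runs on the CPU
    through the package's compact convolutional engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
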