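Package: stclean
Title: Fiducial Marker Removal and Tissue Segmentation for Spatial
    Transcriptomics Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cleans whole-slide hematoxylin-and-eosin images from
    spot-based spatial transcriptomics platforms. Provides a four-stage
    pipeline: segmentation of the circular fiducial alignment markers
    with a customised encoder-decoder convolutional network trained
    under a combined focal and Dice loss, mask-conditioned restoration
    (inpainting) of the marker regions, salient-tissue detection with a
    light trainable saliency network, and segregation of disconnected
    tissue pieces by connected-component labelling. Ships a seeded
    synthetic slide generator with full ground truth, classical
    baselines (Hough circle transform, Otsu thresholding), and a
    segmentation evaluation suite (IoU, Hausdorff distance, perimeter
    ratio, component difference, SSIM, mutual information, multi-class
    Dice, adjusted Rand index, cell morphology descriptors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jpeg,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
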