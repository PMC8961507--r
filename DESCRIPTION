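Package: eunet
Title: Elastomeric U-Net Architectures for Medical Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compiler, trainer, and evaluation toolkit for elastomeric U-Net
    (EUNet) segmentation architectures: horizontally cascaded (single/double/
    three high-peak and low-peak W-shaped networks) and spatially parallel
    (double- and triple-branch) U-shaped convolutional networks. Architectures
    are declared in a compact notation such as "U_1(4-4)-U_2(4-4)" or
    "U_1(4)//U^1(4)", parsed into a validated specification, compiled into an
    explicit layer graph with shape inference, and realized as a trainable
    model with a built-in CPU engine (seeded initialization, Dice loss, Adam,
    batch normalization). Includes pixel-level segmentation metrics (accuracy,
    precision, specificity, mean IoU), DRIVE-style dataset input/output, and a
    seeded generator of synthetic cell and vessel phantoms.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
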