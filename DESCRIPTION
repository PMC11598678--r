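Package: nirvein
Title: Near-Infrared Vein Imaging: Segmentation, Centerline Extraction and
    Variable-Weight AD-Census Stereo Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis toolkit for near-infrared (NIR) vein imaging as
    used in robotic venipuncture guidance. Provides seeded synthetic vein
    phantoms and stereo pairs with ground truth; CLAHE plus median-filter
    preprocessing; Hessian-eigenvalue (vesselness) centerline extraction with
    skeleton refinement; a U-Net segmentation network with a ResNet18 encoder,
    self-supervised BYOL encoder pretraining and parameter transfer, trained
    with hand-derived backpropagation on compiled convolution kernels; a
    variable-weight AD-Census stereo matcher with optimized two-tier
    cross-based cost aggregation; and evaluation metrics (binary
    cross-entropy, IoU, Dice, Hausdorff distance, disparity error rates,
    illuminance uniformity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
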