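Package: maizecount
Title: Sliding-Window CNN Detection and Counting of Corn Kernels on Ear Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and counts corn (Zea mays) kernels on ear photographs with
    a sliding-window pipeline: a small convolutional network scores 32x22
    windows as kernel or non-kernel, greedy non-maximum suppression prunes
    overlapping detections, a second convolutional network regresses the
    sub-pixel kernel center inside each kept window, and the visible-side
    count is extrapolated to a whole-ear estimate with a symmetric-ear
    factor (2.5 by default). Includes a procedural generator of annotated
    synthetic ear scenes (dense near-touching kernels, varied tilt, lighting
    and soil/grass/hand backgrounds) so the full pipeline can be trained and
    evaluated without any external dataset, a HOG+SVM baseline classifier,
    patch-dataset construction with flip/color augmentation, and counting
    accuracy metrics (RMSE, MAE, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    jsonlite,
    e1071,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
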