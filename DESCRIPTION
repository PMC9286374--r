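Package: endopose
Title: Monocular 6D Pose Estimation and Model Overlay for Endoscopic Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for registering a rigid 3D model onto monocular endoscopic
    video frames. A deterministic software renderer simulates labelled surgical
    scenes (target organ or instrument plus occluding tools) with known 6D pose;
    a trainable convolutional encoder-decoder segments frames into
    background/tool/target classes; ellipse fitting on the target mask recovers
    image position, scale and in-plane orientation; a multi-head convolutional
    classifier predicts discretised rotation angles per axis; and a dense
    optical-flow heuristic decomposes masked frame-to-frame motion into
    rotation increments for tracking. A pipeline module composites the posed
    mesh over frames and evaluates segmentation overlap, rotation tolerance
    accuracy and trajectory drift against simulator ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
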