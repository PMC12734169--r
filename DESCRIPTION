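Package: pestdet
Title: Lightweight Single-Stage Crop-Pest Detector Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Modular toolkit for building, profiling, training and evaluating a
    lightweight single-stage detector for crop-pest imagery. Implements
    efficient multi-scale attention (EMA) and efficient channel attention
    (ECA) blocks, adaptive residual feature-extraction blocks with dilated
    separable branches (ARBlock / C3k2-B), a rewired neck/head feature-fusion
    strategy, the Wise-IoU v3 bounding-box regression loss with its dynamic
    non-monotonic focusing mechanism, detection metrics (precision, recall,
    F1, AP, mAP50, mAP50-95, confusion matrices), greedy non-maximum
    suppression, analytic parameter/FLOP profiling of all ablation variants,
    and a seeded synthetic pest-scene generator emulating dense tiny targets
    and elongated leafminer trails, so that every stage is testable at desk
    scale without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
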