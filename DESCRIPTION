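Package: sgrtrack
Title: Surface-Guided Radiotherapy Motion Tracking with a Virtual Depth-Camera Benchmark
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for markerless intra-fraction motion monitoring in
    head-and-neck radiotherapy from surface imaging. Implements robust
    weighted point-to-plane iterative closest point (ICP) registration
    with Barron's generalised adaptive loss, a five-level rough-to-fine
    multiscale schedule, sequential tracking with adaptive region-of-interest
    propagation and warm starts, and fiducial-based rigid calibration of
    depth sensors into the treatment-room frame. A virtual depth-camera
    simulator (parametric head phantom, pinhole z-buffer rendering,
    depth-dependent noise, robot-style motion protocols and facial
    deformations) generates benchmark data entirely in software, and an
    evaluation module computes per-axis tracking-error summaries against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
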