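Package: stemscan
Title: Banana Pseudo-Stem Phenotyping from Mobile LiDAR Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring banana pseudo-stem diameter and height from
    unorganized 3D point clouds acquired with a handheld mobile LiDAR/IMU
    scanner. Implements ground-surface fitting and elevation normalization,
    statistical outlier removal, individual-plant segmentation by height-slab
    Euclidean clustering with footprint-width thresholding and centroid-seeded
    K-means, robust stem diameter estimation (least-squares, Hough transform,
    least-trimmed-squares and RANSAC cylinder fitting), and stem-leaf boundary
    detection with a continuity-based sliding window for height measurement.
    Also provides the scan-line feature-extraction front end (pose
    interpolation and deskew, distance-weighted covariance features,
    point-to-line and point-to-plane residuals) and a labelled synthetic
    orchard generator so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
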