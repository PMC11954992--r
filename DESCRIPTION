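Package: backshape
Title: Back-Surface Asymmetry Analysis for Scoliosis Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the primary Cobb angle and internal spinal alignment of
    scoliosis patients from 3D back-surface point clouds. Implements
    mirror-asymmetry indices and 2 x 17 asymmetry maps built on exact
    nearest-neighbor search and point-to-point iterative closest point (ICP)
    rigid registration, per-posture linear regression to the radiographic Cobb
    angle with a weighted combined estimate, spinous-process-line-based
    estimation of the internal spinal alignment, cohort evaluation statistics
    (Fisher-z confidence intervals, median absolute error, curve RMSE,
    shift-tolerant shape correlation), and a deterministic synthetic
    scoliotic back-surface generator with ground truth for end-to-end
    validation. Point clouds are read and written as PLY, curves and
    landmarks as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
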