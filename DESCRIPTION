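Package: fluorquant
Title: Probability-Mask Quantification of Fluorescent Signal Area,
    Colocalization and Fly Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies fluorescence microscopy signals from pixel-classifier
    probability masks: probability thresholding, connected-component labeling
    with minimum object size filtering, region-of-interest (ROI) normalized
    signal area, binary two-channel colocalization (partial and total),
    corrected total cell fluorescence (CTCF), and an intensity-threshold
    reference segmenter for method-agreement validation. Also computes the
    activity-above-speed-threshold locomotion metric from centroid
    trajectories with an immobility exclusion rule, and rank-based group
    statistics (tie-corrected Kruskal-Wallis, Dunn's post hoc with
    multiplicity adjustment, distribution-free median confidence intervals).
    Ships a synthetic scene and trajectory generator with exact ground truth
    plus a manifest-driven batch pipeline and command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
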