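Package: pamvlt
Title: Integrating Towed-Array Passive Acoustic and Visual Line-Transect
    Surveys for Whale Abundance and Availability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combines simultaneous visual line-transect (VLT) sightings and
    towed-hydrophone passive acoustic (PAM) detections of deep-diving
    whales into a single Bayesian abundance estimate with an in-situ
    estimate of surface availability. Surface abundance is estimated by
    (mark-recapture) distance sampling, subsurface abundance by distance
    sampling of localized acoustic events or by a state-space Jolly-Seber
    capture-recapture model of dive-state transitions fitted to click-train
    capture histories over forward-distance bins. Duplicate detections
    between the two platforms are corrected by counting state transitions
    inside a geometrically derived zone of overlap. Includes a dive-cycle
    and dual-platform detection simulator and tools to run simulation
    studies of the estimators (relative bias, coefficients of variation,
    convergence and posterior-predictive diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
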