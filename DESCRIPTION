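Package: fallfusion
Title: Threshold-Based Fall Detection with Multi-Sensor Decision Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for evaluating threshold-based fall-detection algorithms
    on multi-sensor body-worn accelerometer recordings. Implements four
    classical detectors (basic signal-magnitude-vector thresholding, the
    Yoshida Fall Index, the PerFallD dual-condition windowed detector and the
    two-phase iFall free-fall/impact detector), AND-fusion of per-sensor
    decisions over all combinations of body positions, and a threshold-sweep
    evaluation engine producing sensitivity, specificity, geometric-mean and
    trapezoidal-AUC summaries, including the maximum sensitivity attainable
    under a minimum-specificity constraint. A synthetic trial generator
    emulates a five-position testbed (thigh-pocket smartphone plus chest,
    waist, wrist and ankle motes) with activities of daily living and
    simulated falls, so the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
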