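Package: camtrapnet
Title: Plant-Animal Interaction Networks from Camera-Trap Video and
    Computer-Vision Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building robust plant-animal interaction datasets
    from camera-trap video surveys assisted by computer vision. Implements
    a three-table data standard (deployments, media, observations), parsing
    and aggregation of MegaDetector-format frame-level detections to
    video-level confidence scores, threshold-based blank filtering,
    temporal collapsing of videos into independent interaction events,
    sampling-effort accounting from first and last media timestamps,
    weighted bipartite interaction networks with probability of
    interspecific encounter (PIE) estimates, confusion-matrix validation
    of detector performance (including MCC and species-specific threshold
    calibration curves), lost-information accounting for detector false
    negatives, and two-mode label-permutation QAP tests (valued Hamming
    distance and graph correlation) for comparing networks built with and
    without false-negative imputation. A synthetic-study generator with
    known ground truth supports end-to-end testing and calibration
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    tools,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
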