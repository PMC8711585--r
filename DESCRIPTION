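Package: pitchfatigue
Title: Pitch Fatigue Detection from Pose Keypoints
Version: 0.1.0
Authors@R:
    person("Sam", "Hart", email = "sam.hart@example.com",
           role = c("aut", "cre"))
Description: Detects pitcher fatigue from per-pitch kinematic features.
    Reads OpenPose-dialect keypoint files and pitch-event tables, computes
    the elbow valgus angle, the trunk flexion angle and the inter-pitch
    interval, maps each pitch to per-feature fatigue values via
    piecewise-linear membership functions anchored on non-fatigue and
    fatigue interval statistics, aggregates them into a weighted total
    fatigue index, detects the fatigue point by threshold crossing, and
    evaluates parameter settings with leave-one-game-out cross-validation
    and grid search. A seeded simulator generates feature sessions with a
    known fatigue onset and synthetic keypoint frames realizing prescribed
    angles, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
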