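Package: sowpose
Title: Sow Locomotion Keypoint Simulation, Consensus Scoring and
    Pose-Estimation Metrics
Version: 0.1.0
Authors@R:
    person("RAEB", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating markerless pose estimation of walking
    sows scored for lameness on a 0-3 ordinal locomotion scale.  Provides
    the lateral (6/11/13 keypoint) and dorsal (7/10 keypoint) skeleton
    definitions and a subset algebra between them; a kinematic gait
    simulator that produces ground-truth keypoint tracks with
    score-dependent lameness signatures (stride asymmetry, head dipping,
    back arching, lateral sway) plus a prediction-error model and a
    simulated expert panel; expert-vote consensus via strict majority, the
    difference-between-answers (DBA) statistic and its confidence bands,
    outlier-expert detection and repository filtering; the standard
    keypoint evaluation metrics (object keypoint similarity, mAP/mAR,
    average pixel distance, PCK, per-keypoint pixel-error summaries); and
    dataset bookkeeping (fully-visible-frame filtering, leakage-guarded
    train/test splits, annotation CSV input/output and a command-line
    interface).
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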