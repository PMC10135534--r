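Package: swarmtrack
Title: Anomaly Classification of Insect Flight Trajectories in Mating Swarms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to distinguish a reference class of 3D flight tracks
    (swarming male mosquitoes) from anomalous classes (females and mating
    couples) by one-class classification of fixed-duration track segments.
    Provides track ingestion and quality control, overlapping-window
    segmentation, a trajectory feature battery (kinematics, angular measures,
    orthogonal velocity components, straightness, convex hull, centroid
    distance, curvature, curvature scale space, fractal dimension),
    Mann-Whitney feature screening with Bonferroni correction and correlation
    pruning, a nu-parameterised one-class support vector machine with
    per-track segment voting, leave-two-trials-out cross-validation, grid
    hyperparameter search, sampling-based Shapley feature attribution, and a
    synthetic swarm simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    pROC,
    stats,
    utils,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
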