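Package: ataxiameter
Title: Instrumented Assessment of Upper-Limb Cerebellar Ataxia from Wearable and Camera Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Objective assessment of upper-limb cerebellar ataxia from raw motion
    recordings of four standard bedside tests: finger chase (marker/target
    trajectories from a depth camera), finger tapping, finger-to-nose and
    rapid alternating hand movements (tri-axial accelerometer and gyroscope
    streams). The package extracts a 62-item catalog of kinematic features
    (dynamic-time-warping error, cross-correlation reaction time, Fitts'-law
    kinematic delay, acceleration alterations, inter-tap-interval variability,
    fuzzy entropy, and resonant-frequency/magnitude spectral features), tags
    each feature with a stability/timing/accuracy/rhythmicity domain, screens
    features by backward-elimination selection frequency over resampled
    subsets, classifies ataxic versus control subjects under leave-one-out
    validation (LD, QDA, SVM, KNN), and estimates severity on a 4-level scale
    anchored to the upper-limb SARA score via ridge regression. A synthetic
    cohort generator with graded severity exercises the full pipeline without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    pracma,
    MASS,
    class,
    e1071,
    randomForest,
    glmnet,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
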