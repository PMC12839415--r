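Package: ocatscreen
Title: Oculometric Screening Analysis for Possible Mild Cognitive Impairment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, feature extraction and predictive modeling for a
    one-minute oculo-cognitive addition test (OCAT) used to screen for
    possible mild cognitive impairment. Generates synthetic 120 Hz gaze
    recordings with realistic saccade, fixation, blink and pupil structure;
    performs tracking-ratio quality control, spike correction and blink
    detection; classifies fixations and saccades with a dispersion-threshold
    (I-DT) algorithm and derives a 31-feature oculometric dictionary (6
    time-related, 25 eye-movement-related) plus age; and evaluates
    thresholded L2 logistic regression and k-nearest-neighbour classifiers
    with SMOTE class balancing, two-step feature selection (correlation
    grouping with random-forest importance, then univariate decision-tree
    ROC-AUC filtering) and bootstrapped precision-recall metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    e1071,
    igraph,
    glmnet,
    randomForest,
    rpart,
    pROC,
    class,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
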