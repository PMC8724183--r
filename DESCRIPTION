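Package: msrehab
Title: Personalized Prediction of Upper-Limb Rehabilitation Outcomes in
    Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing upper-limb neurorehabilitation outcomes in
    persons with multiple sclerosis. Computes ten digital health metrics of
    movement and grip-force quality from goal-directed peg-insertion trial
    recordings (smoothness, efficiency, and force-coordination measures with
    confound adjustment and dual-anchor percentage normalization), labels
    considerable improvement in ARAT, BBT and NHPT scores against their
    smallest real differences, and evaluates feature-set by model grids
    (linear regression, decision tree, k-nearest neighbour, random forest)
    with participant-grouped leave-one-subject-out cross-validation.
    Includes the published 20-dataset clinical cohort as a fixture and
    synthetic generators for trials, reference populations and cohorts with
    planted predictor-outcome structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    rpart,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
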