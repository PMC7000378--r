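Package: roiclassify
Title: Atlas-Based Voxel-Count Classification of Task fMRI Contrast Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for classifying two subject groups from task fMRI
    t-statistic maps: thresholds per-subject statistical volumes, counts
    supra-threshold voxels within the parcels of an integer-labelled atlas,
    screens the resulting region features for multicollinearity, selects
    features by recursive elimination under a ridge-penalized logistic
    learner, fits the logistic classifier with demographic covariates, and
    assesses it with stratified train/test splits, test-set subgroup
    cross-validation and a label-shuffle permutation test with escalation.
    Includes a seeded synthetic-cohort generator (atlas parcellation plus
    smoothed Gaussian t-maps with planted regional activation differences)
    so the full pipeline is testable without subject data, and utilities
    for reconstructing confusion matrices from printed metric tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
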