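Package: segcurate
Title: Segmentation Corruption Simulation and DSC-Ranked Auto-Curation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the impact of imperfect reference
    segmentations on trainable organ-at-risk segmenters and for
    auto-curating noisy training cohorts. Provides directional
    morphological corruption operators for binary masks, magnitude
    calibration against a target Dice agreement, a synthetic CT-like
    phantom cohort generator, surface-distance metrics (Dice, mean
    surface distance, Hausdorff), a prompt-training sample-selection
    curation procedure with sensitivity/specificity/agreement scoring,
    logit-averaging ensembles, Wilcoxon/Bonferroni statistics, and
    seeded experiment pipelines, together with a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
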