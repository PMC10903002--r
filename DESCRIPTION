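Package: progdelay
Title: Time-Based Progression Models for Simulated Dementia Trials and
    Health-Economic Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates two-arm longitudinal clinical trials of a
    disease-modifying treatment on the Clinical Dementia Rating Sum of
    Boxes (CDR-SB) scale, with a proportional time-delay treatment
    effect and unstructured multivariate-normal within-subject
    covariance.  Fits the time-based progression model for repeated
    measures (PMRM), in which the treatment effect is a per-visit delay
    in disease time, alongside two conventional comparators: a
    constrained longitudinal (MMRM-style) model measuring effects in
    score points, and a Cox proportional-hazards model on dichotomized
    progression to dementia.  A replication harness computes median
    effect estimates and empirical power over scenario grids, and a
    four-state Markov cohort model translates an estimated slowing of
    progression into long-term time in state by stretching the
    treatment arm's time axis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
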