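Package: vowelpp
Title: Perception-Production Analysis of a Two-Vowel Contrast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for individual differences in the perception
    and production of a two-vowel contrast (American English "head"/"had").
    Fits trial-level logistic psychometric functions to identification data
    and derives the categorical boundary and its 25-75% width (labeling
    consistency); computes per-speaker acoustic production measures on the
    mel scale (vowel contrast distance, 95% coverage-ellipse area, and the
    within-utterance centering ratio); screens cohorts with Shapiro-Wilk
    normality checks and median-absolute-deviation outlier exclusion; and
    runs the Spearman rank-correlation suite relating labeling consistency
    to the production measures. A synthetic-cohort generator with known
    ground truth (logistic listeners, bivariate-Gaussian speakers with a
    tunable self-correction gain) supports parameter-recovery and
    type-I-error testing without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
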