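Package: frontloadr
Title: Transcriptional Frontloading and Cross-Tolerance Analysis for
    Factorial RNA-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies genes responding to an acute stressor under two
    acclimation histories into frontloaded, stress-indicator and
    greater-reaction categories from fold-change reaction ratios and
    constitutive expression, following the frontloading framework used in
    cross-tolerance studies of thermal acclimation and hypoxia. Includes a
    negative-binomial Wald differential-expression stage with
    Benjamini-Hochberg adjustment, median-of-ratios normalization, a
    shifted-log variance-stabilizing transform with batch correction, PCA
    with factorial ANOVA on component scores, physiology ANCOVA with a mass
    covariate, metabolic-rate standardization with gene-expression
    correlation screening, and a synthetic-data generator with known ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    limma,
    car,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
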