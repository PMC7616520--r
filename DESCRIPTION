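Package: targetmr
Title: Drug-Target Mendelian Randomization with Behavioral and Biomarker
    Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-sample Mendelian randomization workflow for contrasting a
    behavioral proxy exposure with the biomarker it is meant to stand in
    for. Provides GWAS summary-statistic input and allele harmonization,
    p-value instrument selection with greedy LD clumping and instrument
    strength statistics, the inverse-variance weighted, MR-Egger, weighted
    median and mode estimators, Steiger directionality testing with
    mechanism-stratified and exposure-reweighted estimation, multivariable
    MR via Q-heterogeneity minimization, a two-way fixed-effects panel
    estimator with two-way cluster-robust standard errors, and a
    structural-equation simulator encoding metabolism-variant titration
    feedback and behavioral pleiotropy with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
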