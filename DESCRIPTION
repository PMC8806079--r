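Package: medsupp
Title: Mediation and Suppression Third-Variable Analysis for Biomarker Cohorts
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the association between an exposure
    biomarker and a continuous health outcome into direct and indirect
    components flowing through one or two intermediate ("third") variables.
    Implements covariate-adjusted linear models with standardized regression
    coefficients, the four-step total/direct/indirect effect decomposition,
    classification of each third variable as a mediator or a suppressor with
    effect percentages, delta-method (Sobel-type) tests of indirect effects,
    and subgroup interaction testing.  Ships a seeded generator of synthetic
    NHANES-like cohorts (serum cotinine, C-reactive protein, body mass index,
    leukocyte telomere length) together with an analytic oracle for the
    population standardized path coefficients the generator implies, so the
    whole pipeline is testable end to end without access to restricted
    survey microdata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
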