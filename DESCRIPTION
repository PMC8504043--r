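Package: rxaudit
Title: Quality Assessment of Medication Prescription Documentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing the documentation quality of hospital drug
    prescriptions before and after the introduction of computerized physician
    order entry (CPOE). Implements a configurable 20-criterion assessment
    engine with met / not met / not applicable ratings, prescription-level and
    criterion-level fulfilment scores, nonparametric and chi-squared cohort
    comparisons, a beta-distributed generalized linear mixed model with
    patient random intercepts estimated by adaptive Gauss-Hermite marginal
    maximum likelihood (with weighted effect coding of wards, odds ratios,
    covariate-adjusted predictions and net interventional effects), E-value
    sensitivity analysis, ward-level change-pattern classification, and a
    synthetic cohort generator for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
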