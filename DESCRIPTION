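Package: indtasd
Title: Scoring and Validation of the AIIMS-Modified INDT-ASD Autism
    Diagnostic Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Executable scoring engine for the AIIMS-Modified INDT-ASD
    instrument, a DSM-5 based diagnostic questionnaire for autism spectrum
    disorder in children: dual-rater response reconciliation, subdomain
    abnormality, the structural diagnostic decision rule, the 0-28 total
    score and score-based severity bands. Also provides the
    diagnostic-accuracy statistics used to validate such instruments
    (sensitivity, specificity and predictive values with Clopper-Pearson
    exact confidence intervals, ROC curves with Youden-optimal cutoffs,
    CARS severity cross-tabulation, Cohen's kappa, Cronbach's alpha,
    Pearson correlation), a seeded synthetic cohort simulator emulating a
    validation study, and a CSV pipeline with command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    e1071,
    optparse,
    jsonlite
Config/testthat/edition: 3
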