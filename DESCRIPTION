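Package: sigdose
Title: Daily Dosage Prediction from Free-Text Prescriptions and
    Construction of Continuous Treatment Periods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts prescribed daily dosage from free-text dosing
    instructions ("sigs") on dispensed prescriptions and converts
    per-dispensation supplies into continuous treatment periods.  A
    two-stage text classifier (an embedding-based dense neural network)
    first flags non-informative texts and then assigns one of sixteen
    daily-dosage classes; unresolved dispensations are imputed by
    carry-forward from the person's recent history and, failing that,
    by a random forest on six structured register features.  Resolved
    dosages are turned into treatment episodes with clamping of
    implausible supply lengths, a non-perfect-adherence extension,
    stockpiling joins and dose-change stratification.  Includes
    validation metrics (Wilson and Wald intervals, weighted g-means,
    error-size bins), downstream usage-pattern analyses (incident-user
    identification with wash-out, Kaplan-Meier discontinuation curves,
    dose categories) and a seeded generator of synthetic Swedish-style
    prescription registers with gold labels so the whole pipeline is
    testable without access to restricted register data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
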