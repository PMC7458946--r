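Package: cifrisk
Title: Quality Risk Modeling for Clinical Trial Audits and Inspections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the risk that a clinical-trial audit or inspection of an
    investigator site yields one or more findings in each of five Clinical
    Impact Factor (CIF) categories: informed consent, safety, data integrity,
    protecting primary endpoints and sponsor oversight. Provides a synthetic
    generator for audit/study/site tables with known ground-truth risk
    structure, hand-crafted binary feature engineering (Yeo-Johnson
    transformation, quantile binning, rare-level grouping, a within-study
    site burden score and a randomization-by-design interaction), one
    logistic regression per CIF with greedy forward selection minimizing
    BIC on an early training window, rolling-origin time-series
    cross-validation that excludes previously audited studies from test
    sets, AUC and Brier backtesting, and a binned step-function calibration
    curve using 75% Wilson confidence intervals with merge-or-default-to-
    base-rate rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    ggplot2
Config/testthat/edition: 3
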