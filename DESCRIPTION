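Package: prothresh
Title: Anchor-Based Interpretability Thresholds (MID and PASS) for
    Patient-Reported Outcome Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates minimal important difference (MID) and patient
    acceptable symptom state (PASS) thresholds for continuous outcome
    instruments against a global-rating-of-change transition anchor.
    Implements the ROC closest-to-top-left-corner cutoff method with
    nonparametric (Mann-Whitney) AUC and DeLong confidence intervals, the
    mean-difference-of-change and mean-change MID estimators, the 75th/25th
    percentile PASS method, percentile-bootstrap confidence intervals,
    Spearman anchor-adequacy diagnostics, and a latent-variable generator
    for synthetic shoulder-trial cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
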