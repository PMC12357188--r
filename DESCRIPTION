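Package: candrift
Title: Performance Drift Monitoring for Percentile-Rank Clinical Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify, explain, and assess the clinical impact of
    performance drift in deployed population health-risk algorithms that rank
    patients by a fixed logistic risk model and flag the top percentiles, as the
    Veterans Health Administration Care Assessment Needs (CAN) score does.
    Provides a longitudinal synthetic-cohort generator with ground-truth
    coefficients and scripted covariate shifts, fixed-coefficient scoring with a
    0-99 within-year percentile transform, the six standard classification
    metrics with exact binomial intervals, calibration by risk decile and AUC,
    baseline-to-final-year drift with individual-level bootstrap confidence
    intervals and affected-patient counts, standardized-mean-difference
    covariate-shift screening against original odds ratios, ablation retraining
    with flagged covariates excluded, and palliative-care quality-metric
    reliability endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
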