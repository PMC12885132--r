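Package: smokeptb
Title: Wildfire Smoke PM2.5 Exposure Metrics and Discrete-Time Models for Preterm Birth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying prenatal exposure to wildfire-derived fine
    particulate matter (PM2.5) and preterm birth. Builds pregnancy-level
    exposure metrics from census-tract daily wildfire PM2.5 series and
    residential histories (mean daily concentration, threshold-exceedance
    smoke days, consecutive-day smoke waves, weekly and cumulative-by-week
    windows); applies cohort inclusion rules that avoid fixed cohort bias and
    expands births into person-period tables; fits pooled logistic regression
    over gestational weeks 22-36 with site random intercepts, week-specific
    critical-window models, a gestational-age linear model, effect-modification
    and sensitivity analyses; performs site-specific multiple imputation by
    chained equations with Rubin pooling; and provides a synthetic cohort
    generator with a known discrete-time hazard, calibrated to published
    cohort marginals, so every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    lme4,
    mgcv,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
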