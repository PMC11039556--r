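Package: idionet
Title: Person-Specific Dynamic Networks of Depressive Symptoms from
    Ecological Momentary Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates person-specific lag-1 graphical vector autoregressive
    (GVAR) networks from intensive longitudinal ecological momentary
    assessment (EMA) data, with full-information maximum likelihood under
    missing beeps and LASSO/BIC regularized fits for visualization. Tests
    whether participants matched on depressive symptom severity (IDS-SR)
    share one network via an AIC-based individual network invariance test
    (INIT), aggregates the per-group decisions into the proportion of
    participants with differential symptom dynamics with a group-resampling
    bootstrap confidence interval, and quantifies the false-detection rate
    of the procedure under a simulated null in which severity-matched
    participants share one true network. Includes a synthetic-data module
    generating stable sparse GVAR processes on the study's 28-day, 5-beep
    grid with missing-at-random beeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
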