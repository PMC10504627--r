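Package: routinewatch
Title: Behavioral Change Detection from Passive Smartphone Monitoring
Version: 0.1.0
Authors@R:
    person("Routinewatch", "Developers", email = "routinewatch@example.org",
           role = c("aut", "cre"))
Description: Turns raw smartphone sensor streams (GPS fixes, step counts,
    app-usage events) into half-hourly daily behavioral features, fits
    per-patient heterogeneous mixture models (Gaussian and Bernoulli
    dimensions) with BIC model selection, detects behavioral change points
    with a Bayesian online change-point detector over the daily profile
    sequence (Dirichlet-categorical observation model, exact marginalization
    of missing days), raises one-week risk alarms via a stability threshold
    on the cumulative 7-day change probability, and evaluates day-level
    alarm performance with pooled ROC/AUC. Includes a synthetic cohort
    generator with planted behavioral patterns, change points, risk events,
    and missingness for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
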