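Package: troutlake
Title: Acoustic Telemetry Analysis of Lake-Migrating Sea Trout
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A file-to-file reproducible pipeline for positional acoustic
    telemetry of anadromous brown trout (sea trout) in a regulated
    lake-river system: seeded simulation of tracks and detections,
    receiver clock-drift synchronisation from fixed sync tags,
    time-of-arrival multilateration with multi-start selection and
    error-based acceptance, rule-based false-detection filtering,
    0-255 sensor payload decoding (acceleration, depth), per-minute
    habitat time budgets with interpolation, and the behavioural
    statistical models: a Poisson count model with offset and gamma
    log-link additive smooth models with factor-by smoothers, random
    intercepts and AR(1) residuals, plus AIC comparison and
    collinearity and concurvity screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
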