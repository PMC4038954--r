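Package: hrrkit
Title: Heart Rate Recovery and RR-Interval Spectral Analysis for Exercise Testing
Version: 0.1.0
Authors@R:
    person("HRR", "Maintainers", email = "maintainers@hrrkit.invalid", role = c("aut", "cre"))
Description: Tools for analysing beat-by-beat heart rate dynamics around a
    symptom-limited exercise test: conversion of beat times to RR tachograms
    with artifact rejection, heart-rate-recovery statistics at 1, 2 and 3
    minutes (absolute, normalised to peak heart rate, and normalised to
    heart-rate reserve), power spectral analysis of the recovery tachogram by
    Welch, autoregressive (Levinson-Durbin) and Lomb-Scargle estimators with
    VLF/LF/HF band powers and normalised units, and a cohort statistics layer
    (group comparisons, Fisher exact tests, and multivariable linear models
    with backward elimination). Includes a seeded synthetic exercise-test
    cohort generator based on integral pulse frequency modulation (IPFM) so
    that every stage of the pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
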