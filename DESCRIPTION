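Package: somnokit
Title: Sleep Homeostasis, Cortical Temperature and EEG State Metrics for
    Rodent Sleep-Deprivation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational analysis of rodent sleep-deprivation
    experiments recorded as epoch-scored hypnograms with per-epoch EEG power
    spectra, cortical-temperature traces and locomotor-activity counts.
    Implements the two-process model's homeostatic Process S (exponential
    saturating dynamics) with exhaustive grid-search fitting of its time
    constants to NREM-sleep EEG delta power, including asymptote estimation
    from delta-power distributions, steady-state warm-up and detrending;
    NREM delta-power percentile time courses; theta-peak frequency and
    theta-dominated-waking classification; NTC-thermistor beta-equation
    temperature conversion and transition-aligned cortical-temperature
    profiles; waking/locomotion partial-correlation and nested mixed-model
    comparison; recovery-versus-baseline sleep accounting; and RT-qPCR
    normalized relative quantities with 3'UTR isoform ratios. A fully
    parameterized synthetic-study generator with known ground truth makes
    every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'core-records.R'
    'process-s.R'
    'qpcr.R'
    'recovery-stats.R'
    'spectral-metrics.R'
    'synthetic-data.R'
    'thermometry.R'
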