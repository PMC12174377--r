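Package: tacsbeta
Title: Sensorimotor EEG Power Analysis for Beta-tACS Aftereffect Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing sensorimotor EEG power around
    20 Hz transcranial alternating current stimulation (tACS): Morlet-wavelet
    time-frequency decomposition, region-of-interest band power with
    event-related desynchronization/synchronization (ERD/ERS) aggregation,
    per-trial peak beta frequency statistics, Gaussian log-link mixed-model
    contrasts, and cluster-based permutation Spearman correlation tests.
    Includes a seeded synthetic-study generator (resting and self-paced
    finger-press recordings with a co-recorded force trace, written as EDF)
    with injectable stimulation aftereffects, so every stage can be
    validated by parameter recovery without access to raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    glmmTMB,
    car,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
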