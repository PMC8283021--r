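Package: cardioresp
Title: Cardiorespiratory and Sleep Phenotyping for Rodent Telemetry and Plethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of murine cardiorespiratory recordings:
    summarization of arterial blood-pressure telemetry into circadian
    light/dark phase means, spectral heart-rate-variability analysis (LF, HF,
    LF/HF from the beat-interval series), breath-by-breath analysis of
    whole-body plethysmography airflow (tidal volume, respiratory rate,
    minute ventilation, inspiratory flow limitation), estimation of the
    hypoxic ventilatory response from a normoxia-to-hypoxia challenge,
    rule-based EEG/EMG sleep staging in 10-s epochs, and scoring of
    sleep-disordered-breathing events (apneas and oxygen desaturations).
    Ships a synthetic-signal generator with ground-truth annotations that
    emulates the full study design (telemetry, polysomnography, hypoxic
    challenge) so every pipeline stage is testable without animal data, plus
    EDF and CSV signal I/O and nonparametric group-comparison reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
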