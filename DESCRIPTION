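Package: dpmtrace
Title: Decision Process Matrices for Tracing Diagnostic Reasoning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recording, validating and analysing Decision Process
    Matrices (DPM): event-log style traces of diagnostic decision-making in
    which suspected diagnoses (options), clinical information units (cues)
    and 9-point confidence ratings are stamped with their order of
    occurrence. Provides a versioned JSON and CSV file format with strict
    validation, automatic segmentation of a trace into the option
    generation, option verification and final determination phases,
    per-case and cohort descriptive statistics, rater-concordance and
    effect-size analytics, and a calibrated stochastic generator of
    synthetic DPM cohorts for method development when observational data
    are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
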