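Package: chronoecg
Title: Circadian Analysis of Longitudinal ECG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for long-term electrocardiogram (ECG) telemetry and
    polysomnography-derived recordings in mouse and human: R-wave detection by
    amplitude thresholding with template-matching beat filtering, species-specific
    PQRST fiducial delineation, sweep-level quality control, a robust geometric
    heart-rate-variability measure based on relative RR intervals, cosinor
    rhythmometry with circular acrophase statistics, cross-correlogram phase-delay
    estimation, locomotor-activity coupling analyses, and rule-based ventricular
    arrhythmia calling. Includes a synthetic ECG/behaviour generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
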