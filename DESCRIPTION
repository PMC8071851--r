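Package: breathsync
Title: Kuramoto-Coupled Breathing Sonification and Respiration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, testable implementation of a respiratory biofeedback
    sonification system. Keypress-logged inhale/exhale onsets are converted to a
    continuously defined breathing phase and tempo, a stimulus oscillator is
    coupled to the breather with a Kuramoto phase/frequency update, and
    synchronization (circular mean resultant length) gates a bounded phase
    delay used to steer breathing toward slower rates and a 1:2 inhale:exhale
    ratio. Three stimulus families (breath-like filtered pink noise, a
    procedurally generated nature scene with phase-driven spatial width, and a
    marimba-like arpeggio with ii-V-I resolution timed to the exhale) are
    rendered to WAV. A virtual breather closes the loop without human subjects,
    and an analysis pipeline extracts respiration rate and ratio timeseries
    (sliding-median smoothing, SD-based outlier rejection, 0.1 Hz resampling,
    log transform) and fits fourth-order orthogonal-polynomial growth curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
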