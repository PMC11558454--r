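Package: rivalcall
Title: Dyadic Vocal Rival Interactions and Mate-Choice Preference Strength
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying dyadic vocal rival interactions and
    two-alternative mate choice in chorusing frogs. Implements rule-based
    segmentation of joint calling bouts from two-male call-event timelines,
    background-corrected RMS and peak-to-peak call amplitude with
    calibration-tone dB referencing, per-pair calling metrics with absolute
    and proportional (Weber-scaled) rival differences, playback-stimulus
    eligibility filtering, a deviation-from-equal-choices preference-strength
    statistic with its binomial response coding, and a random-choice
    Monte-Carlo null distribution with an exact-enumeration oracle. A
    synthetic-data generator produces antiphonal call timelines, audio
    waveforms with ground truth, and choice datasets so the full pipeline
    runs and is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
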