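Package: bildsim
Title: Simulated Remote Assessment of the Binaural Intelligibility Level Difference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A simulation-and-analysis pipeline for remote measurement of the
    binaural intelligibility level difference (BILD) with antiphasic
    speech-in-noise stimuli. Synthesizes spectrum-shaped masking noise and
    binaural trial stimuli, drives a two-down/one-up adaptive 3AFC staircase
    against simulated psychometric listeners, executes a multi-day session
    protocol (quiet run plus three randomized blocks of diotic and antiphasic
    masked runs), generates calibrated synthetic cohorts of children and
    adults, and provides the statistical stage: group summaries, two-way
    consistency intraclass correlations with exact F-based confidence
    intervals, one-tailed Pearson and Welch tests, regression prediction
    bands for outlier screening, and audibility checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
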