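Package: rqol
Title: Momentary Reward-Related Quality of Life from Experience Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the momentary reward-related quality of life (rQoL)
    statistic for Experience Sampling Method (ESM) diary data. rQoL combines
    within-person centered positive affect with the cumulative occurrence
    frequency of the current behavior setting (the Who-What-Where context of a
    beep). The package provides the full pipeline: loading and validity
    filtering of long-format beep records, behavior-setting encoding at three
    granularities with category collapsing, per-subject frequency and
    cumulative-proportion tables, the rQoL reward function, a Monte Carlo
    resampling suite that characterizes the sampling behavior of the statistic
    (unique-setting saturation, rQoL spread, subject contextual-variability
    percentiles, affect-rQoL correlation), and a calibrated synthetic ESM data
    generator so every analysis runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
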