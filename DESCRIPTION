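Package: insulinrl
Title: Tabular Q-Learning for Basal Insulin Dose-Interval Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a dosing policy for long-acting (glargine) insulin in type 1
    diabetes from visit-level clinical trajectories using tabular Q-learning.
    Patient state is a discrete 4-tuple (glycated-hemoglobin band, body-mass-index
    bin, physical-activity category, alcohol-usage category; 306 states) and the
    action is one of six insulin dose intervals. Includes offline experience-replay
    and online epsilon-greedy training, greedy policy extraction, a seedable
    synthetic-cohort simulator with a known ground-truth dose requirement for
    policy-recovery testing, and an interval-match evaluation harness with a
    packaged 60-case test table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
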