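Package: shakebox
Title: Discriminability Models and Exploration-Time Analysis for Shaking-Box Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing children's exploratory play in hidden-numerosity
    shaking-box experiments. Implements an equal-variance signal-detection model of
    numerosity discriminability with log-spaced means (the approximate-number-system
    d-prime), heuristic difficulty alternatives (absolute difference and number
    ratio), an ideal-observer accuracy link for two-alternative forced choice,
    playtime normalization with a cluster-robust regression battery, per-child slope
    summaries, binomial choice-proportion analyses, a synthetic trial generator with
    counterbalanced designs for parameter-recovery studies, and a reproducible
    simulate-analyze-compare-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    ggplot2,
    sandwich,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
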