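Package: ppemonitor
Title: Pose-Landmark Monitoring of Personal Protective Equipment Adherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-level monitoring of personal protective equipment (PPE)
    adherence from anatomical pose landmarks. Implements landmark-driven
    square region-of-interest extraction (face, torso, palms), per-region
    binary classifier heads (dropout, dense, ReLU, sigmoid) trained with
    Adam and binary cross-entropy over a pluggable feature extractor,
    visible-region adherence aggregation, and the full agreement-statistics
    protocol (accuracy, Cohen's kappa, McNemar, Pearson chi-square, Wald
    confidence margins, sample-size estimation). A deterministic synthetic
    schematic-person scene generator provides fully labelled frames and
    events so the whole pipeline runs and is testable without any image
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
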