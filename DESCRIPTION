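Package: ironcog
Title: Blood-Brain-Behavior Analysis of Iron Biofortification Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing randomized iron-biofortification feeding
    trials that measure blood iron biomarkers, EEG features, and behavioral
    task performance at baseline and endline. Implements iron-status
    classification (anemia, IDA, IDNA, Cook body iron), 2x2 group-by-assessment
    difference-in-differences contrasts, AIC-constrained plausibility
    regressions of change scores on biomarker changes, sign-aligned composite
    Z-scores for attention and memory, and moderated-mediation models with
    bootstrap confidence intervals and falsification (direct-only and
    scrambled) alternatives. A seeded synthetic-cohort generator emulates the
    study design so every stage is testable without subject-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
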