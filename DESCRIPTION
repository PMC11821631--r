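Package: tmgtwitch
Title: Twitch Torque and Tensiomyography Analysis of Potentiation and Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse electrically evoked muscle twitches recorded
    simultaneously as knee-extension torque and tensiomyographic (TMG) radial
    muscle-belly displacement. Provides a synthetic-session generator that
    emulates a post-activation-potentiation/fatigue exercise protocol,
    stimulus-triggered signal extraction (Butterworth low-pass filtering,
    rolling-median MVIC, twitch peak torque, displacement amplitude and timing
    parameters), derived contraction-velocity metrics, test-retest reliability
    (ICC, standard error of measurement, minimal detectable change),
    sphericity-corrected repeated-measures inference, and minimal-detectable-
    change based responder classification with full diagnostic-accuracy
    assessment (sensitivity, specificity, predictive values, Youden's index,
    exact binomial intervals, AUROC) of TMG parameters against peak twitch
    torque.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
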