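Package: actipat
Title: Physical Activity Patterns, Clinical Scores and Gamma Regression for
    Nursing-Home Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 60-second epoch activity labels (walking,
    standing, sitting, lying) recorded from thigh- and back-worn accelerometers
    in institutional care settings. Validates and segments label streams into
    24-hour records; computes daily time-use, activity bout histograms and
    sedentary-to-active posture transition counts; scores the Nursing Home
    version of the Neuropsychiatric Inventory (NPI-NH) into subsyndromes, the
    Short Physical Performance Battery (SPPB), and Clinical Dementia Rating
    based severity groups; compares groups with tie-corrected Kruskal-Wallis
    and Dunn post-hoc tests; and fits gamma log-link generalized linear models
    relating activity metrics to neuropsychiatric symptoms and physical
    function. A semi-Markov synthetic cohort generator with known ground truth
    supports end-to-end testing, parameter-recovery and type-I-error studies.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
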