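Package: flankgame
Title: Gamified Adaptive Flanker Assessment Engine, Simulation, and Psychometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for a gamified, difficulty-adaptive child
    Flanker task: fixed and adaptive trial scheduling, a response-window
    staircase controller, response classification (correct, commission,
    omission), and reward-jar feedback. Includes a synthetic respondent
    cohort simulator with age-graded reaction-time and accuracy profiles,
    per-session conflict-effect scoring, and the cohort-level statistics
    used to validate such assessments (paired tests with Cohen's d,
    Fisher-z correlation intervals, 2x2 mixed ANOVA with partial eta
    squared, chi-square tests of independence). All user-facing functions
    take and return tidy data frames.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
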