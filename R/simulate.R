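#' Simulate a full within-subject feasibility study
#'
#' Draws a synthetic cohort, then runs every child through both task
#' conditions with counterbalanced order (odd-numbered children play the
#' gamified condition first), collects enjoyment ratings after each
#' condition and the forced-choice preference after both, and scores all
#' sessions. Each condition uses one seeded trial schedule shared by all
#' children, as a fixed stimulus sequence would be in the deployed task.
#' All randomness descends from `seed` through per-child sub-streams.
#'
#' @param n_children Number of children.
#' @param seed Integer master seed.
#' @param calibration Preset passed to [make_cohort()].
#' @param age_mix Named age proportions passed to [make_cohort()].
#' @param conditions Conditions to administer (default both).
#' @param staircase A [staircase_config()] for the gamified condition.
#' @param fixed_window_ms Traditional-condition deadline, ms.
#' @return An `fg_study` list: `cohort` (child profiles), `trials` (every
#'   trial of every session), `sessions` (one row per child x condition
#'   with `enjoyment`, `preference`, `preferred`), `metrics`
#'   ([compute_metrics()] output), and `seed`.
#' @examples
#' \donttest{
#' study <- simulate_study(n_children = 6, seed = 42)
#' study$metrics
#' }
#' @export
simulate_study <- function(n_children = 20, seed = 1L,
                           calibration = "paper2024",
                           age_mix = c("3" = 0.3, "4" = 0.3, "5" = 0.4),
                           conditions = c("TRADITIONAL", "GAMIFIED"),
                           staircase = staircase_config(),
                           fixed_window_ms = 1700) {
  seed <- as.integer(seed)
  cohort <- make_cohort(n_children, age_mix, calibration, seed)
  configs <- list(
    TRADITIONAL = task_config("TRADITIONAL", fixed_window_ms = fixed_window_ms,
                              seed = child_seed(seed, 999983)),
    GAMIFIED = task_config("GAMIFIED", staircase = staircase,
                           seed = child_seed(seed, 999979)))
  schedules <- lapply(configs[conditions], generate_schedule)

  trials <- list()
  session_rows <- list()
  for (i in seq_len(n_children)) {
    child <- cohort[i, ]
    ga_first <- i %% 2 == 1
    pref <- withr::with_seed(child_seed(seed + 104729L, i),
                             sample_preference(child))
    for (cond in conditions) {
      order_position <- if (length(conditions) == 1) "FIRST"
        else if ((cond == "GAMIFIED") == ga_first) "FIRST" else "SECOND"
      sess <- run_session(
        configs[[cond]], responder_from_profile(child, cond),
        schedule = schedules[[cond]],
        child_id = child$child_id, age_years = child$age_years,
        order_position = order_position,
        seed = child_seed(seed + 15485863L,
                          2L * i + (cond == "GAMIFIED")))
      trials[[length(trials) + 1L]] <- sess
      session_rows[[length(session_rows) + 1L]] <- tibble(
        session_id = sess$session_id[1], child_id = child$child_id,
        age_years = child$age_years, condition = cond,
        order_position = order_position,
        first_condition = if (ga_first) "GAMIFIED" else "TRADITIONAL",
        enjoyment = sample_enjoyment(child, cond),
        preference = pref,
        preferred = (cond == "GAMIFIED" && pref == "GA") ||
          (cond == "TRADITIONAL" && pref == "FLANKER"))
    }
  }
  trials <- dplyr::bind_rows(trials)
  sessions <- dplyr::bind_rows(session_rows)
  structure(
    list(cohort = cohort, trials = trials, sessions = sessions,
         metrics = compute_metrics(trials), seed = seed),
    class = "fg_study")
}

#' @export
print.fg_study <- function(x, ...) {
  cat(sprintf(
    "Simulated flanker study: %d children, %d sessions, %d trials (seed %d)\n",
    nrow(x$cohort), nrow(x$sessions), nrow(x$trials), x$seed))
  invisible(x)
}
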