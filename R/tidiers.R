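#' Tidy a paired test result
#'
#' @param x A `paired_test` object.
#' @param ... Unused.
#' @return A one-row tibble: `estimate` (mean difference), `sd_diff`,
#'   `std.error`, `statistic` (t), `df`, `conf.low`, `conf.high`,
#'   `cohens_d`, `p.value`, `n`.
#' @export
tidy.paired_test <- function(x, ...) {
  tibble(estimate = x$mean_diff, sd_diff = x$sd_diff, std.error = x$se,
         statistic = x$t, df = x$df, conf.low = x$ci95[1],
         conf.high = x$ci95[2], cohens_d = x$cohens_d, p.value = x$p,
         n = x$n)
}

#' @rdname tidy.paired_test
#' @export
glance.paired_test <- function(x, ...) tidy(x, ...)

#' Tidy a correlation result
#'
#' @param x A `correlation_result` object.
#' @param ... Unused.
#' @return A one-row tibble: `estimate` (r), `conf.low`, `conf.high`,
#'   `p.value`, `n`.
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble(estimate = x$r, conf.low = x$ci95[1], conf.high = x$ci95[2],
         p.value = x$p, n = x$n)
}

#' Tidy a mixed ANOVA result
#'
#' @param x An `anova_result` object.
#' @param ... Unused.
#' @return A tibble with one row per effect: `term`, `df1`, `df2`,
#'   `statistic` (F), `p.value`, `partial_eta_sq`.
#' @export
tidy.anova_result <- function(x, ...) {
  e <- x$effects
  tibble(term = e$effect, df1 = e$df1, df2 = e$df2, statistic = e$F,
         p.value = e$p, partial_eta_sq = e$partial_eta_sq)
}

#' Tidy a chi-square result
#'
#' @param x A `chisq_result` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `n`.
#' @export
tidy.chisq_result <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p,
         n = sum(x$observed))
}

#' Tidy a full study analysis into one long table
#'
#' @param x A `study_analysis` object.
#' @param ... Unused.
#' @return A tibble with one row per statistic: `analysis`, `term`,
#'   `estimate`, `statistic`, `conf.low`, `conf.high`, `p.value`, `n`.
#' @export
tidy.study_analysis <- function(x, ...) {
  rows <- list()
  add_pt <- function(analysis, term, pt) {
    t <- tidy(pt)
    rows[[length(rows) + 1L]] <<- tibble(
      analysis = analysis, term = term, estimate = t$estimate,
      statistic = t$statistic, conf.low = t$conf.low,
      conf.high = t$conf.high, p.value = t$p.value, n = t$n)
  }
  for (nm in names(x$conflict_tests))
    add_pt("conflict_test", nm, x$conflict_tests[[nm]])
  for (nm in names(x$condition_tests))
    add_pt("condition_comparison", nm, x$condition_tests[[nm]])
  if (!is.null(x$cross_condition))
    rows[[length(rows) + 1L]] <- x$cross_condition %>%
      mutate(analysis = "cross_condition_correlation", term = .data$metric,
             estimate = .data$r, statistic = NA_real_, p.value = .data$p) %>%
      select(all_of(c("analysis", "term", "estimate", "statistic",
                      "conf.low", "conf.high", "p.value", "n")))
  if (!is.null(x$covariate_cors))
    rows[[length(rows) + 1L]] <- x$covariate_cors %>%
      mutate(analysis = "covariate_correlation",
             term = paste(.data$metric, .data$covariate, .data$condition,
                          sep = "|"),
             estimate = .data$r, statistic = NA_real_, p.value = .data$p) %>%
      select(all_of(c("analysis", "term", "estimate", "statistic",
                      "conf.low", "conf.high", "p.value", "n")))
  if (!is.null(x$enjoyment_anova))
    rows[[length(rows) + 1L]] <- tidy(x$enjoyment_anova) %>%
      mutate(analysis = "enjoyment_anova", estimate = .data$partial_eta_sq,
             conf.low = NA_real_, conf.high = NA_real_, n = NA_integer_) %>%
      select(all_of(c("analysis", "term", "estimate", "statistic",
                      "conf.low", "conf.high", "p.value", "n")))
  if (!is.null(x$preference) && !is.null(x$preference$chisq))
    rows[[length(rows) + 1L]] <- tidy(x$preference$chisq) %>%
      mutate(analysis = "preference_chisq", term = "preference_x_order",
             estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_) %>%
      select(all_of(c("analysis", "term", "estimate", "statistic",
                      "conf.low", "conf.high", "p.value", "n")))
  dplyr::bind_rows(rows)
}

#' Study-level summary
#'
#' @param x An `fg_study` object from [simulate_study()].
#' @param ... Unused.
#' @return A one-row tibble: children, sessions, trials, seed.
#' @export
glance.fg_study <- function(x, ...) {
  tibble(n_children = nrow(x$cohort), n_sessions = nrow(x$sessions),
         n_trials = nrow(x$trials), seed = x$seed)
}
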