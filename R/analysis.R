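#' Run the full cohort-level analysis battery
#'
#' Given per-session metrics and the session-level enjoyment/preference
#' table (and optionally the cohort table with covariates), computes the
#' statistics a within-subject feasibility analysis of the two task
#' conditions reports:
#' * per-condition congruent-vs-incongruent paired tests for accuracy and
#'   RT (signed so a positive effect is the conflict effect),
#' * cross-condition Pearson correlations (incongruent/congruent/overall
#'   accuracy, incongruent RT, both conflict scores),
#' * gamified-vs-traditional paired tests on the conflict scores and on
#'   incongruent accuracy,
#' * correlations of incongruent accuracy and RT with the verbal and
#'   matrix covariates (when `cohort` is supplied),
#' * a 2x2 mixed ANOVA on enjoyment (order between, condition within),
#' * preference shares and a chi-square test of preference x task order.
#'
#' RT-based paired comparisons drop children with an undefined RT mean
#' (no correct trials in a congruency class) pairwise; the n actually
#' used is reported with each result. Values are kept at full precision;
#' rounding is for rendering only (see [report_md()]).
#'
#' @param metrics A metrics tibble from [compute_metrics()], both
#'   conditions per child.
#' @param sessions A session table with `child_id`, `condition`,
#'   `first_condition`, `enjoyment`, `preference` (see [simulate_study()]).
#' @param cohort Optional cohort tibble with `verbal_score` and
#'   `matrix_score`.
#' @return A `study_analysis` object; `tidy()` flattens every statistic
#'   into one long tibble.
#' @export
run_study_analysis <- function(metrics, sessions, cohort = NULL) {
  if (dplyr::n_distinct(metrics$child_id) < 2)
    abort("need at least 2 children with both conditions",
          class = "flankgame_stat_error")
  wide <- metrics %>%
    select(all_of(c("child_id", "condition", "acc_congruent", "acc_incongruent",
                    "acc_overall", "rt_congruent_ms", "rt_incongruent_ms",
                    "conflict_rt_ms", "conflict_acc"))) %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = -all_of(c("child_id", "condition")))

  conflict_tests <- list()
  for (cond in unique(metrics$condition)) {
    m <- metrics[metrics$condition == cond, ]
    conflict_tests[[paste0("acc_", cond)]] <-
      with_step(paste("accuracy conflict,", cond),
                paired_test(m$acc_congruent, m$acc_incongruent))
    ok <- !is.na(m$rt_congruent_ms) & !is.na(m$rt_incongruent_ms)
    conflict_tests[[paste0("rt_", cond)]] <-
      with_step(paste("RT conflict,", cond),
                paired_test(m$rt_incongruent_ms[ok], m$rt_congruent_ms[ok]))
  }

  both <- all(c("TRADITIONAL", "GAMIFIED") %in% metrics$condition)
  cross <- NULL; condition_tests <- list()
  if (both) {
    cross_vars <- c("acc_incongruent", "acc_congruent", "acc_overall",
                    "rt_incongruent_ms", "conflict_rt_ms", "conflict_acc")
    cross <- dplyr::bind_rows(lapply(cross_vars, function(v) {
      a <- wide[[paste0(v, "_GAMIFIED")]]
      b <- wide[[paste0(v, "_TRADITIONAL")]]
      ok <- !is.na(a) & !is.na(b)
      res <- with_step(paste("cross-condition correlation of", v),
                       pearson_with_ci(a[ok], b[ok]))
      tibble(metric = v, r = res$r, conf.low = res$ci95[1],
             conf.high = res$ci95[2], p = res$p, n = res$n)
    }))
    condition_tests$conflict_acc <- with_step(
      "conflict accuracy, gamified vs traditional",
      paired_test(wide$conflict_acc_GAMIFIED, wide$conflict_acc_TRADITIONAL))
    ok <- !is.na(wide$conflict_rt_ms_GAMIFIED) &
      !is.na(wide$conflict_rt_ms_TRADITIONAL)
    condition_tests$conflict_rt <- with_step(
      "conflict RT, gamified vs traditional",
      paired_test(wide$conflict_rt_ms_GAMIFIED[ok],
                  wide$conflict_rt_ms_TRADITIONAL[ok]))
    condition_tests$acc_incongruent <- with_step(
      "incongruent accuracy, gamified vs traditional",
      paired_test(wide$acc_incongruent_GAMIFIED,
                  wide$acc_incongruent_TRADITIONAL))
  }

  covariate_cors <- NULL
  if (!is.null(cohort)) {
    cov_long <- metrics %>%
      left_join(select(cohort, all_of(c("child_id", "verbal_score",
                                        "matrix_score"))), by = "child_id")
    grid <- expand.grid(metric = c("acc_incongruent", "rt_incongruent_ms"),
                        covariate = c("verbal_score", "matrix_score"),
                        condition = unique(metrics$condition),
                        stringsAsFactors = FALSE)
    covariate_cors <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      m <- cov_long[cov_long$condition == g$condition, ]
      ok <- !is.na(m[[g$metric]]) & !is.na(m[[g$covariate]])
      res <- with_step(
        paste("covariate correlation:", g$metric, "x", g$covariate, g$condition),
        pearson_with_ci(m[[g$metric]][ok], m[[g$covariate]][ok]))
      tibble(condition = g$condition, metric = g$metric,
             covariate = g$covariate, r = res$r, conf.low = res$ci95[1],
             conf.high = res$ci95[2], p = res$p, n = res$n)
    }))
  }

  enjoyment_anova <- NULL; preference <- NULL
  if (!is.null(sessions)) {
    if (both && all(c("enjoyment", "first_condition") %in% names(sessions)))
      enjoyment_anova <- with_step(
        "mixed ANOVA on enjoyment",
        mixed_anova_2x2(sessions, dv = "enjoyment", within = "condition",
                        between = "first_condition", id = "child_id"))
    if ("preference" %in% names(sessions)) {
      per_child <- sessions %>%
        group_by(.data$child_id) %>%
        summarise(preference = .data$preference[1],
                  first_condition = .data$first_condition[1],
                  .groups = "drop")
      shares <- table(factor(per_child$preference,
                             levels = c("GA", "FLANKER", "NONE")))
      tab <- table(per_child$preference, per_child$first_condition)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      chisq <- if (nrow(tab) >= 2 && ncol(tab) >= 2)
        with_step("chi-square of preference x order",
                  chi_square_independence(tab)) else NULL
      preference <- list(
        counts = shares, share_ga = 100 * unname(shares["GA"]) / sum(shares),
        chisq = chisq)
    }
  }

  n_tests <- length(conflict_tests) + length(condition_tests) +
    (if (is.null(cross)) 0 else nrow(cross)) +
    (if (is.null(covariate_cors)) 0 else nrow(covariate_cors)) +
    (if (is.null(enjoyment_anova)) 0 else nrow(enjoyment_anova$effects)) +
    (if (is.null(preference) || is.null(preference$chisq)) 0 else 1)

  structure(
    list(conflict_tests = conflict_tests, cross_condition = cross,
         condition_tests = condition_tests, covariate_cors = covariate_cors,
         enjoyment_anova = enjoyment_anova, preference = preference,
         n_tests = n_tests),
    class = "study_analysis")
}

# name the failing analysis step when propagating errors
with_step <- function(step, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("analysis step failed [%s]: %s", step, conditionMessage(e)),
          class = "flankgame_analysis_error")
  })
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("Study analysis (", x$n_tests, " statistical tests, no multiplicity",
      " correction)\n", sep = "")
  for (nm in names(x$conflict_tests)) {
    cat(nm, ": "); print(x$conflict_tests[[nm]])
  }
  if (!is.null(x$preference))
    cat(sprintf("Gamified preference share: %.0f%%\n", x$preference$share_ga))
  invisible(x)
}

#' Round half away from zero
#'
#' Report-time rounding rule: halves round away from zero (2.675 -> 2.68
#' at 2 digits), unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Render a study analysis as markdown
#'
#' Writes a human-readable report of every statistic in a
#' `study_analysis`, rounded to 2 decimals (half-up) at render time only.
#'
#' @param analysis A `study_analysis` from [run_study_analysis()].
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return The markdown lines, invisibly when written to `path`.
#' @export
report_md <- function(analysis, path = NULL) {
  r2 <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)
  pt_line <- function(label, pt) sprintf(
    "- %s: M = %s, SD = %s, SE = %s, t(%d) = %s, 95%% CI [%s, %s], d = %s, p = %.3g (n = %d)",
    label, r2(pt$mean_diff), r2(pt$sd_diff), r2(pt$se), pt$df, r2(pt$t),
    r2(pt$ci95[1]), r2(pt$ci95[2]), r2(pt$cohens_d), pt$p, pt$n)
  lines <- c("# Flanker study analysis", "", "## Conflict effects")
  for (nm in names(analysis$conflict_tests))
    lines <- c(lines, pt_line(nm, analysis$conflict_tests[[nm]]))
  if (!is.null(analysis$cross_condition)) {
    lines <- c(lines, "", "## Cross-condition correlations")
    cc <- analysis$cross_condition
    lines <- c(lines, sprintf(
      "- %s: r = %s, 95%% CI [%s, %s], p = %.3g (n = %d)",
      cc$metric, r2(cc$r), r2(cc$conf.low), r2(cc$conf.high), cc$p, cc$n))
  }
  if (length(analysis$condition_tests) > 0) {
    lines <- c(lines, "", "## Condition comparisons")
    for (nm in names(analysis$condition_tests))
      lines <- c(lines, pt_line(nm, analysis$condition_tests[[nm]]))
  }
  if (!is.null(analysis$covariate_cors)) {
    lines <- c(lines, "", "## Covariate correlations")
    cv <- analysis$covariate_cors
    lines <- c(lines, sprintf(
      "- %s x %s (%s): r = %s, p = %.3g (n = %d)",
      cv$metric, cv$covariate, cv$condition, r2(cv$r), cv$p, cv$n))
  }
  if (!is.null(analysis$enjoyment_anova)) {
    lines <- c(lines, "", "## Enjoyment (mixed ANOVA)")
    e <- analysis$enjoyment_anova$effects
    lines <- c(lines, sprintf(
      "- %s: F(%d, %d) = %s, p = %.3g, partial eta^2 = %s",
      e$effect, e$df1, e$df2, r2(e$F), e$p, r2(e$partial_eta_sq)))
  }
  if (!is.null(analysis$preference)) {
    lines <- c(lines, "", "## Preference",
               sprintf("- Gamified chosen by %s%% of children",
                       r2(analysis$preference$share_ga)))
    if (!is.null(analysis$preference$chisq)) {
      ch <- analysis$preference$chisq
      lines <- c(lines, sprintf(
        "- Preference x order: chi-square(%d, N = %d) = %s, p = %.3g",
        ch$df, sum(ch$observed), r2(ch$chi2), ch$p))
    }
  }
  lines <- c(lines, "", sprintf("%d tests run; no multiple-testing correction applied.",
                                analysis$n_tests))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
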