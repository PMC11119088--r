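#' Paired-sample t test with paired Cohen's d
#'
#' Two-sided paired t test with the reporting fields used for small
#' within-subject designs: mean difference, SD of the differences, its
#' standard error, t, df, an exact-t 95% CI, the paired Cohen's d (mean
#' difference over SD of differences, equal to t / sqrt(n)), and p. The
#' sign convention is `mean(x - y)`.
#'
#' @param x,y Paired numeric samples of equal length (n >= 2), no missing
#'   pairs.
#' @return A `paired_test` object; see [tidy.paired_test()].
#' @examples
#' paired_test(c(5, 7, 9, 6), c(4, 6, 5, 5))
#' @export
paired_test <- function(x, y) {
  if (length(x) != length(y))
    abort("paired samples must have equal length", class = "flankgame_stat_error")
  if (length(x) < 2)
    abort("paired test needs at least 2 pairs", class = "flankgame_stat_error")
  if (anyNA(x) || anyNA(y))
    abort("missing pairs are not allowed", class = "flankgame_stat_error")
  d <- x - y
  if (stats::sd(d) == 0) {
    # degenerate case: constant differences (e.g., x identical to y)
    m <- mean(d)
    return(structure(
      list(mean_diff = m, sd_diff = 0, n = length(d), se = 0, df = length(d) - 1,
           t = if (m == 0) 0 else sign(m) * Inf, ci95 = c(m, m),
           cohens_d = if (m == 0) 0 else sign(m) * Inf,
           p = if (m == 0) 1 else 0),
      class = "paired_test"))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  out <- paired_result(mean(d), stats::sd(d), length(d))
  # identical formulas; keep t.test as the computational route for the
  # data-based entry point
  out$t <- unname(ht$statistic)
  out$p <- ht$p.value
  out$ci95 <- as.numeric(ht$conf.int)
  out
}

#' Paired-sample statistics from printed summaries
#'
#' Reconstructs the full paired-test report (`t`, `se`, exact-t 95% CI,
#' Cohen's d, p) from a printed mean difference, SD of differences, and
#' n — so published summary tables can be checked directly.
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff SD of the paired differences (> 0).
#' @param n Number of pairs (>= 2).
#' @return A `paired_test` object.
#' @examples
#' paired_from_summary(25.65, 11.71, 20)  # t = 9.80, d = 2.19
#' @export
paired_from_summary <- function(mean_diff, sd_diff, n) {
  if (n < 2 || n != round(n))
    abort("n must be an integer >= 2", class = "flankgame_stat_error")
  if (sd_diff <= 0)
    abort("sd_diff must be positive", class = "flankgame_stat_error")
  paired_result(mean_diff, sd_diff, n)
}

paired_result <- function(mean_diff, sd_diff, n) {
  se <- sd_diff / sqrt(n)
  df <- n - 1
  t <- mean_diff / se
  crit <- qt(0.975, df)
  structure(
    list(mean_diff = mean_diff, sd_diff = sd_diff, n = n, se = se, df = df,
         t = t, ci95 = c(mean_diff - crit * se, mean_diff + crit * se),
         cohens_d = mean_diff / sd_diff,
         p = 2 * pt(-abs(t), df)),
    class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired t test: M = %.2f, SD = %.2f, SE = %.2f, t(%d) = %.2f, 95%% CI [%.2f, %.2f], d = %.2f, p = %.3g\n",
    x$mean_diff, x$sd_diff, x$se, x$df, x$t, x$ci95[1], x$ci95[2],
    x$cohens_d, x$p))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with a 95% CI from the Fisher
#' transformation (`atanh(r) +/- 1.96 / sqrt(n - 3)`, back-transformed)
#' and a two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), finite, each with
#'   nonzero variance.
#' @return A `correlation_result` object with `r`, `n`, `ci95`, `p`.
#' @examples
#' pearson_with_ci(1:10, (1:10) + rnorm(10))
#' @export
pearson_with_ci <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    abort("correlation needs equal-length samples with n >= 4",
          class = "flankgame_stat_error")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    abort("inputs must be finite and complete", class = "flankgame_stat_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("zero variance input", class = "flankgame_stat_error")
  n <- length(x)
  ht <- stats::cor.test(x, y)
  r <- unname(ht$estimate)
  z <- atanh(r)
  half <- qnorm(0.975) / sqrt(n - 3)
  structure(
    list(r = r, n = n, ci95 = tanh(c(z - half, z + half)), p = ht$p.value),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, n = %d, 95%% CI [%.3f, %.3f], p = %.3g\n",
              x$r, x$n, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}

#' 2x2 mixed-design ANOVA with partial eta squared
#'
#' Classical sums-of-squares decomposition for one between-subject factor
#' (e.g., task order) crossed with one within-subject factor (e.g.,
#' condition), the design used to test enjoyment for order effects.
#' Effects reported: between, within, and their interaction, each with
#' `F`, dfs, `p`, and partial eta squared
#' (`SS_effect / (SS_effect + SS_error_of_that_effect)`).
#'
#' @param data A data frame with one row per subject x within-level.
#' @param dv,within,between,id Column names (strings) of the response,
#'   the within factor, the between factor, and the subject identifier.
#' @return An `anova_result` object; effects in a tibble with columns
#'   `effect`, `df1`, `df2`, `F`, `p`, `partial_eta_sq`.
#' @export
mixed_anova_2x2 <- function(data, dv, within, between, id) {
  df <- data.frame(
    y = data[[dv]],
    w = factor(data[[within]]), b = factor(data[[between]]),
    s = factor(data[[id]]))
  counts <- table(df$s, df$w)
  if (any(counts != 1))
    abort("every subject needs exactly one row per within level",
          class = "flankgame_stat_error")
  if (any(rowSums(table(df$s, df$b) > 0) != 1))
    abort("the between factor must be constant within subject",
          class = "flankgame_stat_error")
  fit <- stats::aov(y ~ b * w + Error(s / w), data = df)
  sm <- summary(fit)
  between_tab <- as.data.frame(sm[["Error: s"]][[1]])
  within_tab <- as.data.frame(sm[["Error: s:w"]][[1]])
  pull <- function(tab, term) {
    i <- which(trimws(rownames(tab)) == term)
    j <- which(trimws(rownames(tab)) == "Residuals")
    ss <- tab[i, "Sum Sq"]; ss_err <- tab[j, "Sum Sq"]
    tibble(df1 = tab[i, "Df"], df2 = tab[j, "Df"],
           F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
           partial_eta_sq = ss / (ss + ss_err))
  }
  effects <- dplyr::bind_rows(
    mutate(pull(between_tab, "b"), effect = between, .before = 1),
    mutate(pull(within_tab, "w"), effect = within, .before = 1),
    mutate(pull(within_tab, "b:w"),
           effect = paste(between, within, sep = ":"), .before = 1))
  structure(list(effects = effects), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("%s: F(%d, %d) = %.2f, p = %.3g, partial eta^2 = %.2f\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i],
                e$partial_eta_sq[i]))
  invisible(x)
}

#' Chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` on a contingency table of
#' counts, df = (rows - 1)(cols - 1), without continuity correction.
#'
#' @param observed A matrix or table of non-negative integer counts, at
#'   least 2 x 2, with no all-zero row or column.
#' @return A `chisq_result` object with `chi2`, `df`, `p`, `observed`,
#'   `expected`.
#' @examples
#' chi_square_independence(matrix(c(10, 0, 0, 10), 2))
#' @export
chi_square_independence <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(observed != round(observed)))
    abort("counts must be non-negative integers", class = "flankgame_stat_error")
  if (nrow(observed) < 2 || ncol(observed) < 2)
    abort("need at least a 2 x 2 table", class = "flankgame_stat_error")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    abort("zero row or column total", class = "flankgame_stat_error")
  ht <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  structure(
    list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, observed = observed,
         expected = unname(ht$expected)),
    class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square(%d, N = %d) = %.2f, p = %.3g\n",
              x$df, sum(x$observed), x$chi2, x$p))
  invisible(x)
}
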