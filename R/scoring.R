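#' Conflict scores from congruency-wise summaries
#'
#' The flanker conflict effect as a signed difference: for reaction time,
#' incongruent minus congruent (positive = slowing under conflict); for
#' accuracy, congruent minus incongruent (positive = accuracy cost of
#' conflict).
#'
#' @param congruent,incongruent Congruency-wise means (accuracy in
#'   percent, or RT in ms).
#' @param type `"accuracy"` or `"rt"`.
#' @return The signed conflict score.
#' @examples
#' conflict_score(88.43, 62.78, "accuracy")  # 25.65
#' conflict_score(1656.45, 2046.10, "rt")    # 389.65
#' @export
conflict_score <- function(congruent, incongruent, type = c("accuracy", "rt")) {
  type <- match.arg(type)
  if (type == "accuracy") congruent - incongruent else incongruent - congruent
}

#' Per-session performance metrics
#'
#' Computes test-block metrics for every session in a trial table:
#' accuracy by congruency and overall (percent of test trials correct;
#' omissions and commissions both count against accuracy), mean RT by
#' congruency over correct trials only (`NA` when a congruency class has
#' no correct trials, never a silent 0), the signed conflict scores, and
#' omission/commission counts. Practice trials are excluded. No rounding
#' happens here; round only when rendering.
#'
#' @param trials A trial tibble from [run_session()] (one or many sessions
#'   row-bound), or read back via [read_event_log()].
#' @param rt_include_commissions If `TRUE`, commission RTs enter the RT
#'   means as a sensitivity analysis; default `FALSE` (correct trials
#'   only).
#' @return A tibble with one row per session: `session_id`, `child_id`,
#'   `age_years`, `condition`, `order_position`, the accuracy/RT fields,
#'   `conflict_rt_ms`, `conflict_acc`, `n_omissions`, `n_commissions`,
#'   `n_test`.
#' @export
compute_metrics <- function(trials, rt_include_commissions = FALSE) {
  test <- trials[trials$phase == "TEST", , drop = FALSE]
  if (nrow(test) == 0)
    abort("no test trials: malformed or truncated log", class = "flankgame_log_error")
  rt_ok <- if (rt_include_commissions) c("CORRECT", "COMMISSION") else "CORRECT"
  test %>%
    group_by(.data$session_id, .data$child_id, .data$age_years,
             .data$condition, .data$order_position) %>%
    summarise(
      acc_congruent = 100 * mean(.data$outcome[.data$congruency == "CONGRUENT"] == "CORRECT"),
      acc_incongruent = 100 * mean(.data$outcome[.data$congruency == "INCONGRUENT"] == "CORRECT"),
      acc_overall = 100 * mean(.data$outcome == "CORRECT"),
      rt_congruent_ms = mean_or_na(
        .data$rt_ms[.data$congruency == "CONGRUENT" & .data$outcome %in% rt_ok]),
      rt_incongruent_ms = mean_or_na(
        .data$rt_ms[.data$congruency == "INCONGRUENT" & .data$outcome %in% rt_ok]),
      n_omissions = sum(.data$outcome == "OMISSION"),
      n_commissions = sum(.data$outcome == "COMMISSION"),
      n_test = dplyr::n(),
      .groups = "drop") %>%
    mutate(
      conflict_rt_ms = .data$rt_incongruent_ms - .data$rt_congruent_ms,
      conflict_acc = .data$acc_congruent - .data$acc_incongruent)
}

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

#' Omission counts by age and condition
#'
#' Mean and SD (n - 1 denominator) of per-session omission counts in each
#' age x condition cell. The SD is `NA` for single-session cells; empty
#' cells are simply absent from the output rather than reported as zero.
#'
#' @param metrics A metrics tibble from [compute_metrics()].
#' @return A tibble with `age_years`, `condition`, `mean_omissions`,
#'   `sd_omissions`, `n`.
#' @export
omission_summary <- function(metrics) {
  metrics %>%
    group_by(.data$age_years, .data$condition) %>%
    summarise(mean_omissions = mean(.data$n_omissions),
              sd_omissions = if (dplyr::n() > 1) stats::sd(.data$n_omissions) else NA_real_,
              n = dplyr::n(), .groups = "drop")
}
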