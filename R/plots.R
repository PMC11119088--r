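#' Plot the conflict effect by condition
#'
#' Dot-and-summary plot of per-session accuracy (or correct-trial RT) on
#' congruent vs incongruent trials, faceted by condition. The vertical
#' gap between congruencies is the conflict effect.
#'
#' @param metrics A metrics tibble from [compute_metrics()].
#' @param what `"accuracy"` or `"rt"`.
#' @return A ggplot object.
#' @export
plot_conflict <- function(metrics, what = c("accuracy", "rt")) {
  what <- match.arg(what)
  cols <- if (what == "accuracy") {
    c(CONGRUENT = "acc_congruent", INCONGRUENT = "acc_incongruent")
  } else {
    c(CONGRUENT = "rt_congruent_ms", INCONGRUENT = "rt_incongruent_ms")
  }
  long <- metrics %>%
    select(all_of(c("child_id", "condition", unname(cols)))) %>%
    tidyr::pivot_longer(all_of(unname(cols)), names_to = "congruency",
                        values_to = "value") %>%
    mutate(congruency = names(cols)[match(.data$congruency, cols)]) %>%
    filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$congruency, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$child_id), alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 3) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(y = if (what == "accuracy") "Accuracy (%)"
                  else "Mean correct RT (ms)", x = NULL)
}

#' Plot enjoyment ratings by condition
#'
#' @param sessions A session table with `condition` and `enjoyment`.
#' @return A ggplot object.
#' @export
plot_enjoyment <- function(sessions) {
  ggplot2::ggplot(sessions,
                  ggplot2::aes(x = .data$enjoyment, fill = .data$condition)) +
    ggplot2::geom_dotplot(binwidth = 0.2, position = "identity", alpha = 0.6) +
    ggplot2::scale_x_continuous(limits = c(0.5, 5.5), breaks = 1:5) +
    ggplot2::labs(x = "Enjoyment rating (1-5)", y = NULL)
}

#' Plot adaptive window trajectories
#'
#' Response-window course over gamified test trials, one line per
#' session: how far each child's staircase descended.
#'
#' @param trials A trial tibble containing gamified sessions.
#' @return A ggplot object.
#' @export
plot_window_trajectory <- function(trials) {
  ga <- trials %>%
    filter(.data$condition == "GAMIFIED", .data$phase == "TEST") %>%
    group_by(.data$session_id) %>%
    mutate(test_trial = dplyr::row_number()) %>%
    ungroup()
  ggplot2::ggplot(ga, ggplot2::aes(x = .data$test_trial, y = .data$window_ms,
                                   group = .data$session_id)) +
    ggplot2::geom_step(alpha = 0.4) +
    ggplot2::labs(x = "Test trial", y = "Allotted window (ms)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Default plot for a simulated study
#'
#' @param object An `fg_study` from [simulate_study()].
#' @param ... Unused.
#' @return A ggplot object (accuracy conflict plot).
#' @export
autoplot.fg_study <- function(object, ...) plot_conflict(object$metrics)
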