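#' Initialize staircase state
#'
#' @param config A [staircase_config()].
#' @return A `staircase_state` list: `window_ms` (currently allotted
#'   response window), `streak` (consecutive correct responses since the
#'   last change or reset), `decrements_applied`, and `trials_seen`
#'   (needed only by block mode).
#' @examples
#' staircase_init(staircase_config())
#' @export
staircase_init <- function(config) {
  validate_staircase_config(config)
  structure(
    list(window_ms = config$start_window_ms, streak = 0L,
         decrements_applied = 0L, trials_seen = 0L),
    class = "staircase_state")
}

#' Advance the staircase by one trial outcome
#'
#' The controller that adapts task difficulty to real-time performance: a
#' correct response extends the streak, and when the streak reaches
#' `streak_target` the response window shrinks by `step_ms` (clamped at
#' `floor_ms`) and the streak resets. A commission or omission resets the
#' streak and leaves the window untouched, so difficulty stagnates under
#' errors. In `"block"` mode the decrement decision is instead taken at
#' each `streak_target`-trial block boundary and requires an all-correct
#' block.
#'
#' @param state A `staircase_state` from [staircase_init()].
#' @param outcome `"CORRECT"`, `"COMMISSION"`, or `"OMISSION"`.
#' @param config The owning [staircase_config()].
#' @return The updated `staircase_state`.
#' @examples
#' s <- staircase_init(staircase_config())
#' s <- staircase_update(s, "CORRECT", staircase_config())
#' @export
staircase_update <- function(state, outcome, config) {
  if (!outcome %in% OUTCOMES)
    abort(sprintf("unknown outcome '%s'", outcome), class = "flankgame_contract_error")
  state$trials_seen <- state$trials_seen + 1L
  state$streak <- if (outcome == "CORRECT") state$streak + 1L else 0L
  decrement_now <- if (config$mode == "streak") {
    state$streak >= config$streak_target
  } else {
    state$trials_seen %% config$streak_target == 0L &&
      state$streak >= config$streak_target
  }
  if (decrement_now) {
    state$decrements_applied <- state$decrements_applied + 1L
    state$window_ms <- max(config$floor_ms,
                           config$start_window_ms -
                             state$decrements_applied * config$step_ms)
    state$streak <- 0L
  }
  if (config$mode == "block" && state$trials_seen %% config$streak_target == 0L)
    state$streak <- 0L
  state
}

#' Replay a full outcome sequence through the staircase
#'
#' @param outcomes Character vector of `"CORRECT"` / `"COMMISSION"` /
#'   `"OMISSION"`.
#' @param config A [staircase_config()].
#' @return A tibble with one row per trial: `trial` (1-based), `outcome`,
#'   `window_before_ms` (the window allotted to that trial), and
#'   `window_after_ms` (the window after applying the outcome).
#' @examples
#' staircase_replay(rep("CORRECT", 6), staircase_config())
#' @export
staircase_replay <- function(outcomes, config) {
  state <- staircase_init(config)
  before <- after <- numeric(length(outcomes))
  for (i in seq_along(outcomes)) {
    before[i] <- state$window_ms
    state <- staircase_update(state, outcomes[i], config)
    after[i] <- state$window_ms
  }
  tibble(trial = seq_along(outcomes), outcome = outcomes,
         window_before_ms = before, window_after_ms = after)
}
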