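#' Staircase controller configuration
#'
#' Parameters of the adaptive response-window controller used in the
#' gamified condition. After `streak_target` consecutive correct responses
#' the allotted response window shrinks by `step_ms`; any error or timeout
#' stalls the window where it is. The window never drops below `floor_ms`.
#'
#' @param start_window_ms Opening response window in ms. The gamified task
#'   opens far above the traditional 1700 ms deadline so that even the
#'   slowest children respond in time early on; the staircase then titrates
#'   downward.
#' @param step_ms Decrement applied after each completed correct streak, ms.
#' @param streak_target Number of consecutive correct responses that earns
#'   one decrement.
#' @param floor_ms Hard lower bound on the window, ms.
#' @param n_levels Number of hidden 3-trial levels the test block is split
#'   into; `streak_target * n_levels` must equal the test-trial count of the
#'   owning [task_config()].
#' @param mode `"streak"` (default): a rolling streak counter that persists
#'   across level boundaries. `"block"`: the decrement decision is taken
#'   only at 3-trial block boundaries, requiring an all-correct block.
#'
#' @return A `staircase_config` list.
#' @examples
#' staircase_config()
#' @export
staircase_config <- function(start_window_ms = 8000, step_ms = 500,
                             streak_target = 3, floor_ms = 500,
                             n_levels = 14, mode = c("streak", "block")) {
  mode <- match.arg(mode)
  cfg <- structure(
    list(start_window_ms = start_window_ms, step_ms = step_ms,
         streak_target = streak_target, floor_ms = floor_ms,
         n_levels = n_levels, mode = mode),
    class = "staircase_config")
  validate_staircase_config(cfg)
  cfg
}

validate_staircase_config <- function(cfg) {
  if (cfg$start_window_ms <= 0 || cfg$floor_ms <= 0)
    abort("staircase windows must be positive durations", class = "flankgame_config_error")
  if (cfg$floor_ms > cfg$start_window_ms)
    abort("floor_ms may not exceed start_window_ms", class = "flankgame_config_error")
  if (cfg$step_ms < 0)
    abort("step_ms may not be negative", class = "flankgame_config_error")
  if (cfg$streak_target < 1 || cfg$streak_target != round(cfg$streak_target))
    abort("streak_target must be a positive integer", class = "flankgame_config_error")
  if (cfg$n_levels < 1 || cfg$n_levels != round(cfg$n_levels))
    abort("n_levels must be a positive integer", class = "flankgame_config_error")
  invisible(cfg)
}

#' Task configuration for one condition
#'
#' Bundles every fixed and adaptive parameter of one administration of the
#' flanker task. Defaults mirror the published design: 8 practice trials,
#' 42 test trials at a 67:33 congruent:incongruent ratio, a 450 ms
#' inter-trial interval, and a fixed 1700 ms response deadline in the
#' traditional condition. The gamified condition replaces the fixed test
#' deadline with the staircase controller; practice trials use the fixed
#' `practice_window_ms` in both conditions.
#'
#' @param condition `"TRADITIONAL"` or `"GAMIFIED"`.
#' @param n_practice Number of practice trials (half congruent).
#' @param n_test Number of test trials. Must be divisible by the staircase
#'   block size in the gamified condition.
#' @param congruent_fraction Proportion of test trials that are congruent,
#'   strictly between 0 and 1. Realized counts use largest-remainder
#'   rounding (28/14 at defaults).
#' @param iti_ms Inter-trial interval, ms.
#' @param fixed_window_ms Response deadline for traditional test trials, ms.
#' @param staircase A [staircase_config()]; used only when
#'   `condition = "GAMIFIED"`.
#' @param practice_window_ms Response deadline for practice trials in both
#'   conditions, ms.
#' @param practice_pass_min_correct Minimum correct responses in a practice
#'   block to proceed to the test block.
#' @param max_practice_repeats Maximum number of times a failed practice
#'   block is re-presented before proceeding regardless.
#' @param seed Integer seed that fixes the trial order; identical
#'   `(config, seed)` yields an identical schedule.
#'
#' @return A `task_config` list.
#' @examples
#' task_config("GAMIFIED", seed = 1)
#' @export
task_config <- function(condition = c("TRADITIONAL", "GAMIFIED"),
                        n_practice = 8, n_test = 42,
                        congruent_fraction = 2 / 3,
                        iti_ms = 450, fixed_window_ms = 1700,
                        staircase = staircase_config(),
                        practice_window_ms = 1700,
                        practice_pass_min_correct = 6,
                        max_practice_repeats = 2,
                        seed = 1L) {
  condition <- match.arg(condition)
  cfg <- structure(
    list(condition = condition, n_practice = n_practice, n_test = n_test,
         congruent_fraction = congruent_fraction, iti_ms = iti_ms,
         fixed_window_ms = fixed_window_ms, staircase = staircase,
         practice_window_ms = practice_window_ms,
         practice_pass_min_correct = practice_pass_min_correct,
         max_practice_repeats = max_practice_repeats,
         seed = as.integer(seed)),
    class = "task_config")
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  counts <- c(cfg$n_practice, cfg$n_test, cfg$max_practice_repeats)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("trial counts must be non-negative integers", class = "flankgame_config_error")
  if (cfg$congruent_fraction <= 0 || cfg$congruent_fraction >= 1)
    abort("congruent_fraction must lie strictly between 0 and 1", class = "flankgame_config_error")
  if (cfg$iti_ms <= 0 || cfg$fixed_window_ms <= 0 || cfg$practice_window_ms <= 0)
    abort("all durations must be positive", class = "flankgame_config_error")
  if (cfg$condition == "GAMIFIED") {
    validate_staircase_config(cfg$staircase)
    blk <- cfg$staircase$streak_target
    if (cfg$n_test %% blk != 0)
      abort(sprintf("n_test (%d) must be divisible by the staircase block size (%d)",
                    cfg$n_test, blk), class = "flankgame_config_error")
    if (cfg$staircase$n_levels * blk != cfg$n_test)
      abort(sprintf("staircase n_levels (%d) x streak_target (%d) must equal n_test (%d)",
                    cfg$staircase$n_levels, blk, cfg$n_test),
            class = "flankgame_config_error")
  }
  invisible(cfg)
}
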