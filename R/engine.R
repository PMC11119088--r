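#' Classify a single trial response
#'
#' Deadline-based outcome classification: no response is an omission; a
#' response after the allotted window is coerced to omission (a late
#' response is a non-response); a timely response in the wrong direction is
#' a commission; a timely response matching the target is correct.
#'
#' @param target `"LEFT"` or `"RIGHT"`: the direction of the central
#'   target.
#' @param response `"LEFT"`, `"RIGHT"`, or `"NONE"`.
#' @param rt_ms Response time in ms, or `NA` iff `response = "NONE"`.
#' @param window_ms Allotted response window, ms.
#' @return `"CORRECT"`, `"COMMISSION"`, or `"OMISSION"`.
#' @examples
#' classify_response("LEFT", "LEFT", 900, 1700)
#' classify_response("LEFT", "RIGHT", 900, 1700)
#' classify_response("LEFT", "NONE", NA, 1700)
#' @export
classify_response <- function(target, response, rt_ms, window_ms) {
  if (!response %in% RESPONSES)
    abort(sprintf("unknown response '%s'", response), class = "flankgame_contract_error")
  if (response == "NONE") {
    if (!is.na(rt_ms))
      abort("rt_ms must be absent when response is NONE", class = "flankgame_contract_error")
    return("OMISSION")
  }
  if (is.na(rt_ms) || rt_ms < 0)
    abort("rt_ms must be a non-negative duration for a response",
          class = "flankgame_contract_error")
  if (rt_ms > window_ms) return("OMISSION")
  if (response == target) "CORRECT" else "COMMISSION"
}

#' Update the reward jar
#'
#' The gamified condition's visible progress feedback: a correct response
#' banks one treasure; an error (commission or omission) lets the opponent
#' take one, never below an empty jar.
#'
#' @param jar_count Current non-negative treasure count.
#' @param outcome `"CORRECT"`, `"COMMISSION"`, or `"OMISSION"`.
#' @return The updated count.
#' @examples
#' update_jar(5, "CORRECT")
#' update_jar(0, "COMMISSION")
#' @export
update_jar <- function(jar_count, outcome) {
  if (!outcome %in% OUTCOMES)
    abort(sprintf("unknown outcome '%s'", outcome), class = "flankgame_contract_error")
  if (jar_count < 0)
    abort("jar_count must be non-negative", class = "flankgame_contract_error")
  if (outcome == "CORRECT") jar_count + 1L else max(0L, jar_count - 1L)
}

#' Run one session of the task
#'
#' Iterates the schedule, querying `responder` for each trial, classifying
#' outcomes, and (in the gamified condition) updating the staircase window
#' after every test trial and the reward jar after every trial. The
#' practice block is re-presented (same trials, up to
#' `max_practice_repeats` extra times) until at least
#' `practice_pass_min_correct` responses in one pass are correct; repeated
#' practice passes are logged with an incremented `practice_repeat` and
#' never enter test metrics. Traditional test trials all use
#' `fixed_window_ms`; practice trials use `practice_window_ms` in both
#' conditions.
#'
#' @param config A [task_config()].
#' @param responder A function `(trial, window_ms) -> list(response, rt_ms)`
#'   where `trial` is a one-row schedule data frame. `rt_ms` must be `NA`
#'   iff `response` is `"NONE"`. See [responder_perfect()].
#' @param schedule Optional schedule tibble; defaults to
#'   `generate_schedule(config)`.
#' @param child_id,age_years,order_position,session_id Session metadata
#'   copied into every trial row.
#' @param seed Optional integer seed fixing the responder's randomness, so
#'   identical `(config, schedule, responder, seed)` give an identical
#'   session.
#' @return A tibble with one row per administered trial, in order:
#'   `session_id`, `child_id`, `age_years`, `condition`, `order_position`,
#'   `trial_index`, `phase`, `practice_repeat`, `level_index`,
#'   `congruency`, `target`, `window_ms`, `response`, `rt_ms`, `outcome`,
#'   `feedback`, `jar_count` (`NA` in the traditional condition), `iti_ms`.
#' @examples
#' run_session(task_config("GAMIFIED", seed = 3), responder_perfect())
#' @export
run_session <- function(config, responder, schedule = NULL,
                        child_id = "child", age_years = NA_integer_,
                        order_position = NA_character_,
                        session_id = NULL, seed = NULL) {
  validate_task_config(config)
  schedule <- schedule %||% generate_schedule(config)
  session_id <- session_id %||%
    paste0(child_id, "_", tolower(config$condition))
  gamified <- config$condition == "GAMIFIED"

  run <- function() {
    practice <- schedule[schedule$phase == "PRACTICE", , drop = FALSE]
    test <- schedule[schedule$phase == "TEST", , drop = FALSE]
    rows <- list()
    jar <- if (gamified) 0L else NA_integer_

    play_trial <- function(trial, window_ms, practice_repeat) {
      resp <- responder(trial, window_ms)
      if (!is.list(resp) || !all(c("response", "rt_ms") %in% names(resp)) ||
          !is.character(resp$response) || length(resp$response) != 1 ||
          length(resp$rt_ms) != 1 || !resp$response %in% RESPONSES ||
          (resp$response == "NONE") != is.na(resp$rt_ms))
        abort(sprintf("responder returned malformed output at trial index %d",
                      trial$index), class = "flankgame_contract_error")
      response <- resp$response
      rt <- resp$rt_ms
      # a late response is a non-response
      if (!is.na(rt) && rt > window_ms) {
        response <- "NONE"
        rt <- NA_real_
      }
      outcome <- classify_response(trial$target, response, rt, window_ms)
      if (gamified) jar <<- update_jar(jar, outcome)
      rows[[length(rows) + 1L]] <<- list(
        trial_index = trial$index, phase = trial$phase,
        practice_repeat = practice_repeat, level_index = trial$level_index,
        congruency = trial$congruency, target = trial$target,
        window_ms = window_ms, response = response, rt_ms = rt,
        outcome = outcome,
        feedback = if (outcome == "CORRECT") "POSITIVE" else "NEGATIVE",
        jar_count = jar)
      outcome
    }

    # practice: repeat the same block until passed or out of repeats
    if (nrow(practice) > 0) {
      for (rep_i in 0:config$max_practice_repeats) {
        n_correct <- 0L
        for (k in seq_len(nrow(practice))) {
          out <- play_trial(practice[k, ], config$practice_window_ms, rep_i)
          if (out == "CORRECT") n_correct <- n_correct + 1L
        }
        if (n_correct >= config$practice_pass_min_correct) break
      }
    }

    st <- if (gamified) staircase_init(config$staircase)
    for (k in seq_len(nrow(test))) {
      window <- if (gamified) st$window_ms else config$fixed_window_ms
      out <- play_trial(test[k, ], window, NA_integer_)
      if (gamified) st <- staircase_update(st, out, config$staircase)
    }
    rows
  }

  rows <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- dplyr::bind_rows(lapply(rows, as_tibble))
  tibble(session_id = session_id, child_id = child_id,
         age_years = age_years, condition = config$condition,
         order_position = order_position, out, iti_ms = config$iti_ms)
}

#' Deterministic reference responders
#'
#' `responder_perfect()` always answers with the target direction at a
#' fixed latency; `responder_silent()` never responds (every trial times
#' out). Both are useful for exercising the engine's bookkeeping.
#'
#' @param rt_ms Latency of the perfect responder, ms.
#' @return A responder function for [run_session()].
#' @export
responder_perfect <- function(rt_ms = 400) {
  force(rt_ms)
  function(trial, window_ms) list(response = trial$target, rt_ms = rt_ms)
}

#' @rdname responder_perfect
#' @export
responder_silent <- function() {
  function(trial, window_ms) list(response = "NONE", rt_ms = NA_real_)
}
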