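#' Generate the trial schedule for one session
#'
#' Produces the ordered practice and test trial sequence for either
#' condition: `n_practice` practice trials (half congruent, half
#' incongruent, intermixed) followed by `n_test` test trials whose
#' congruency counts are the largest-remainder rounding of
#' `congruent_fraction * n_test` (28 congruent / 14 incongruent at
#' defaults). Left/right targets are balanced within each congruency class,
#' with an odd count giving the extra trial to LEFT. The order is shuffled
#' under the config seed subject to a run-length constraint: never more
#' than 3 consecutive trials of the same congruency nor of the same target
#' direction, enforced by rejection-resampling. In the gamified condition
#' the test block is partitioned into `n_levels` hidden levels of
#' `streak_target` trials (`level_index = floor(test position / 3)`).
#'
#' @param config A [task_config()].
#' @return A tibble with one row per trial: `index` (0-based position in
#'   the whole sequence), `phase`, `congruency`, `target`, and
#'   `level_index` (`NA` outside gamified test trials).
#' @examples
#' generate_schedule(task_config("GAMIFIED", seed = 7))
#' @export
generate_schedule <- function(config) {
  validate_task_config(config)
  withr::with_seed(config$seed, {
    practice <- schedule_block(config$n_practice,
                               n_congruent = config$n_practice %/% 2)
    n_cong <- largest_remainder_congruent(config$congruent_fraction, config$n_test)
    test <- schedule_block(config$n_test, n_congruent = n_cong)
    out <- bind_rows(
      mutate(practice, phase = "PRACTICE"),
      mutate(test, phase = "TEST")
    )
  })
  out$index <- seq_len(nrow(out)) - 1L
  out$level_index <- NA_integer_
  if (config$condition == "GAMIFIED" && config$n_test > 0) {
    test_pos <- seq_len(config$n_test) - 1L
    out$level_index[out$phase == "TEST"] <-
      test_pos %/% config$staircase$streak_target
  }
  as_tibble(out[, c("index", "phase", "congruency", "target", "level_index")])
}

# Largest-remainder rounding of the congruent share of n trials.
largest_remainder_congruent <- function(fraction, n) {
  exact <- fraction * n
  base <- floor(exact)
  if (exact - base >= 0.5) base <- base + 1
  as.integer(base)
}

# One shuffled block with the run-length constraint (max 3 consecutive
# identical congruencies or directions). Congruency order and the
# within-class direction assignment are rejection-resampled in turn; a
# joint resample of the full shuffle is astronomically wasteful at the
# default 28:14 split.
schedule_block <- function(n, n_congruent, max_run = 3L, max_attempts = 1e5) {
  if (n == 0) {
    return(tibble(congruency = character(), target = character()))
  }
  n_incong <- n - n_congruent
  if (n_congruent < 0 || n_incong < 0)
    abort("congruency counts must be non-negative", class = "flankgame_config_error")
  congruency <- resample_until(
    function() sample(c(rep("CONGRUENT", n_congruent), rep("INCONGRUENT", n_incong))),
    function(x) max_run_length(x) <= max_run, max_attempts)
  target <- resample_until(
    function() assign_directions(congruency),
    function(x) max_run_length(x) <= max_run, max_attempts)
  tibble(congruency = congruency, target = target)
}

# 50:50 LEFT/RIGHT within each congruency class; odd counts give the
# extra trial to LEFT.
assign_directions <- function(congruency) {
  out <- character(length(congruency))
  for (cls in unique(congruency)) {
    idx <- which(congruency == cls)
    n_left <- ceiling(length(idx) / 2)
    out[idx] <- sample(c(rep("LEFT", n_left), rep("RIGHT", length(idx) - n_left)))
  }
  out
}

max_run_length <- function(x) if (length(x) == 0) 0L else max(rle(x)$lengths)

resample_until <- function(draw, accept, max_attempts) {
  for (i in seq_len(max_attempts)) {
    x <- draw()
    if (accept(x)) return(x)
  }
  abort("run-length constraint unsatisfiable within attempt budget",
        class = "flankgame_schedule_error")
}

#' Write or read a schedule as CSV
#'
#' One row per trial with columns `index`, `phase`, `congruency`, `target`,
#' `level_index`. The reader restores the column types written by
#' [generate_schedule()].
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param path File path.
#' @return `write_schedule()` returns `schedule` invisibly;
#'   `read_schedule()` returns the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule, path)
  invisible(schedule)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    index = readr::col_integer(), phase = readr::col_character(),
    congruency = readr::col_character(), target = readr::col_character(),
    level_index = readr::col_integer()))
}
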