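EVENT_LOG_KEYS <- c(
  "session_id", "child_id", "age_years", "condition", "order_position",
  "trial_index", "phase", "practice_repeat", "level_index", "congruency",
  "target", "window_ms", "response", "rt_ms", "outcome", "jar_count",
  "iti_ms")

#' Write a session event log as JSONL
#'
#' One JSON object per trial, keys in a fixed order for diff-stability.
#' Fields that are absent for a trial (`rt_ms` on omissions, `level_index`
#' outside gamified test trials, `jar_count` and `practice_repeat` where
#' not applicable) are omitted from the record; the reader restores them
#' as `NA`.
#'
#' @param session A session tibble from [run_session()] (or several
#'   sessions row-bound together).
#' @param path Output file path; `write_event_log()` appends nothing and
#'   overwrites.
#' @return `write_event_log()` returns `session` invisibly;
#'   `read_event_log()` returns a session tibble with the same columns and
#'   types as [run_session()] minus the derived `feedback` column.
#' @export
write_event_log <- function(session, path) {
  lines <- vapply(seq_len(nrow(session)), function(i) {
    row <- as.list(session[i, EVENT_LOG_KEYS])
    row <- row[!vapply(row, is.na, logical(1))]
    jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(session)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  int_cols <- c("age_years", "trial_index", "practice_repeat",
                "level_index", "jar_count")
  dbl_cols <- c("window_ms", "rt_ms", "iti_ms")
  rows <- lapply(recs, function(r) {
    for (k in EVENT_LOG_KEYS) {
      if (is.null(r[[k]]))
        r[[k]] <- if (k %in% int_cols) NA_integer_
                  else if (k %in% dbl_cols) NA_real_ else NA_character_
    }
    r[int_cols] <- lapply(r[int_cols], as.integer)
    r[dbl_cols] <- lapply(r[dbl_cols], as.numeric)
    as_tibble(r[EVENT_LOG_KEYS])
  })
  dplyr::bind_rows(rows)
}
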