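test_that("response classification follows the deadline rules", {
  expect_equal(classify_response("LEFT", "LEFT", 900, 1700), "CORRECT")
  expect_equal(classify_response("LEFT", "RIGHT", 900, 1700), "COMMISSION")
  expect_equal(classify_response("LEFT", "NONE", NA, 1700), "OMISSION")
  # a response after the deadline is a non-response
  expect_equal(classify_response("LEFT", "LEFT", 1701, 1700), "OMISSION")
  expect_equal(classify_response("LEFT", "LEFT", 1700, 1700), "CORRECT")
  expect_error(classify_response("LEFT", "LEFT", -5, 1700),
               class = "flankgame_contract_error")
  expect_error(classify_response("LEFT", "NONE", 900, 1700),
               class = "flankgame_contract_error")
})

test_that("jar gains on correct, loses on errors, clamps at empty", {
  expect_equal(update_jar(5, "CORRECT"), 6)
  expect_equal(update_jar(5, "OMISSION"), 4)
  expect_equal(update_jar(5, "COMMISSION"), 4)
  expect_equal(update_jar(0, "COMMISSION"), 0)
})

test_that("traditional sessions use the fixed window throughout the test block", {
  cfg <- task_config("TRADITIONAL", seed = 4)
  sess <- run_session(cfg, responder_perfect())
  test <- sess[sess$phase == "TEST", ]
  expect_equal(unique(test$window_ms), 1700)
  expect_true(all(is.na(test$jar_count)))
  expect_equal(nrow(sess), 50)
})

test_that("gamified perfect run: no omissions, one step down per 3 test trials", {
  cfg <- task_config("GAMIFIED", seed = 4)
  sess <- run_session(cfg, responder_perfect())
  expect_equal(sum(sess$outcome == "OMISSION"), 0)
  test <- sess[sess$phase == "TEST", ]
  expect_equal(test$window_ms, 8000 - 500 * ((seq_len(42) - 1L) %/% 3L))
  # jar counts every correct trial from the first practice trial on
  expect_equal(tail(sess$jar_count, 1), nrow(sess))
  # practice uses the fixed practice window even in the gamified condition
  expect_equal(unique(sess$window_ms[sess$phase == "PRACTICE"]), 1700)
})

test_that("silent responder: all omissions, practice repeats exhaust, jar stays 0", {
  cfg <- task_config("GAMIFIED", seed = 4)
  sess <- run_session(cfg, responder_silent())
  test <- sess[sess$phase == "TEST", ]
  expect_equal(sum(test$outcome == "OMISSION"), 42)
  expect_true(all(sess$jar_count == 0))
  # failed practice re-presented max_practice_repeats extra times
  expect_equal(sum(sess$phase == "PRACTICE"), 8 * 3)
  expect_equal(sort(unique(sess$practice_repeat)), 0:2)
  m <- compute_metrics(sess)
  expect_equal(m$acc_overall, 0)
  # gamified window never descends without correct streaks
  expect_equal(unique(test$window_ms), 8000)
})

test_that("practice passes on first try for an accurate responder", {
  cfg <- task_config("TRADITIONAL", seed = 4)
  sess <- run_session(cfg, responder_perfect())
  expect_equal(sum(sess$phase == "PRACTICE"), 8)
  expect_equal(unique(stats::na.omit(sess$practice_repeat)), 0)
})

test_that("gamified window sequence matches a standalone staircase replay", {
  cfg <- task_config("GAMIFIED", seed = 10)
  profile <- make_cohort(1, seed = 3)[1, ]
  sess <- run_session(cfg, responder_from_profile(profile, "GAMIFIED"),
                      seed = 77)
  test <- sess[sess$phase == "TEST", ]
  replay <- staircase_replay(test$outcome, cfg$staircase)
  expect_equal(test$window_ms, replay$window_before_ms)
})

test_that("sessions are reproducible under a seed and jar replays from outcomes", {
  cfg <- task_config("GAMIFIED", seed = 10)
  profile <- make_cohort(1, seed = 3)[1, ]
  a <- run_session(cfg, responder_from_profile(profile, "GAMIFIED"), seed = 5)
  b <- run_session(cfg, responder_from_profile(profile, "GAMIFIED"), seed = 5)
  expect_identical(a, b)
  jar <- 0L
  for (i in seq_len(nrow(a))) {
    jar <- update_jar(jar, a$outcome[i])
    expect_equal(a$jar_count[i], jar)
  }
})

test_that("malformed responder output aborts naming the trial", {
  cfg <- task_config("TRADITIONAL", seed = 4)
  bad <- function(trial, window_ms) list(response = "LEFT", rt_ms = NA_real_)
  expect_error(run_session(cfg, bad), regexp = "trial index 0",
               class = "flankgame_contract_error")
})

test_that("event logs round-trip through JSONL", {
  cfg <- task_config("GAMIFIED", seed = 10)
  profile <- make_cohort(1, seed = 3)[1, ]
  sess <- run_session(cfg, responder_from_profile(profile, "GAMIFIED"),
                      child_id = "c001", age_years = 4L,
                      order_position = "FIRST", seed = 5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(sess, path)
  back <- read_event_log(path)
  keep <- setdiff(names(sess), "feedback")
  expect_equal(as.data.frame(back), as.data.frame(sess[, keep]))
  # reader tolerates records without rt_ms
  expect_true(anyNA(back$rt_ms) || all(!is.na(back$rt_ms)))
})
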