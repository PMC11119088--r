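make_profile <- function(...) {
  base <- make_cohort(1, seed = 1)[1, ]
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

test_that("cohorts are reproducible and sub-streams are stable under growth", {
  a <- make_cohort(20, seed = 99)
  b <- make_cohort(20, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 20)
  expect_equal(as.integer(table(a$age_years)), c(6L, 6L, 8L))
  # growing the cohort leaves earlier children untouched
  big <- make_cohort(30, seed = 99)
  shared <- intersect(which(big$age_years[1:20] == a$age_years), 1:20)
  expect_equal(as.data.frame(big[shared, ]), as.data.frame(a[shared, ]))
  expect_error(make_cohort(5, age_mix = c("3" = 0.5, "4" = 0.2, "5" = 0.2)),
               class = "flankgame_config_error")
})

test_that("age presets are monotone: older children are faster and more accurate", {
  p <- age_presets("paper2024")
  expect_true(all(diff(p$mu) < 0))
  expect_true(all(diff(p$err_incong) < 0))
  expect_true(all(diff(p$lapse) < 0))
  old <- make_cohort(50, age_mix = c("3" = 0, "4" = 0, "5" = 1), seed = 1)
  young <- make_cohort(50, age_mix = c("3" = 1, "4" = 0, "5" = 0), seed = 1)
  expect_lt(mean(old$mu), mean(young$mu))
  expect_lt(mean(old$err_incong), mean(young$err_incong))
  expect_error(age_presets("other"), class = "flankgame_config_error")
})

test_that("error-free child with unlimited window is always correct", {
  prof <- make_profile(lapse = 0, err_cong = 0, err_incong = 0)
  trial <- list(congruency = "CONGRUENT", target = "RIGHT")
  withr::local_seed(1)
  for (i in 1:50) {
    r <- sample_response(prof, trial, Inf)
    expect_equal(r$response, "RIGHT")
    expect_true(r$rt_ms > prof$t0_ms)
  }
})

test_that("a window below the non-decision time forces omission", {
  prof <- make_profile(lapse = 0)
  trial <- list(congruency = "CONGRUENT", target = "LEFT")
  withr::local_seed(2)
  for (i in 1:25) {
    r <- sample_response(prof, trial, prof$t0_ms - 1)
    expect_equal(r$response, "NONE")
    expect_true(is.na(r$rt_ms))
  }
})

test_that("congruency penalty matches the lognormal-mean closed form", {
  prof <- make_profile(lapse = 0, mu = 6.8, sigma = 0.35, delta_incong = 0.25,
                       err_cong = 0, err_incong = 0)
  draw_mean <- function(congruency, n) {
    trial <- list(congruency = congruency, target = "LEFT")
    mean(vapply(seq_len(n), function(i)
      sample_response(prof, trial, Inf)$rt_ms, numeric(1)))
  }
  withr::local_seed(31)
  n <- 4e4
  observed_gap <- draw_mean("INCONGRUENT", n) - draw_mean("CONGRUENT", n)
  expected_gap <- exp(prof$mu) * (exp(prof$delta_incong) - 1) *
    exp(prof$sigma^2 / 2)
  # MC standard error of the gap is ~2.5 ms at this n
  expect_lt(abs(observed_gap - expected_gap), 12)
})

test_that("omission probability is non-increasing in the window", {
  prof <- make_profile(lapse = 0.02)
  trial <- list(congruency = "INCONGRUENT", target = "LEFT")
  p_omit <- vapply(c(800, 1200, 1700, 3000, 8000), function(win) {
    withr::local_seed(7)
    mean(vapply(seq_len(3000), function(i)
      sample_response(prof, trial, win)$response == "NONE", logical(1)))
  }, numeric(1))
  expect_true(all(diff(p_omit) <= 0))
  expect_gt(p_omit[1], p_omit[5])
})

test_that("gamified slowdown and conflict ordering hold for the preset", {
  prof <- make_profile(lapse = 0)
  trial <- list(congruency = "CONGRUENT", target = "LEFT")
  withr::local_seed(11)
  rt_trad <- mean(vapply(1:3000, function(i)
    sample_response(prof, trial, Inf, "TRADITIONAL")$rt_ms, numeric(1)))
  rt_ga <- mean(vapply(1:3000, function(i)
    sample_response(prof, trial, Inf, "GAMIFIED")$rt_ms, numeric(1)))
  expect_gt(rt_ga, rt_trad)
})

test_that("enjoyment favors the gamified condition; zero shift implies identity", {
  cohort <- make_cohort(400, seed = 21)
  ga <- vapply(seq_len(400), function(i)
    sample_enjoyment(cohort[i, ], "GAMIFIED"), integer(1))
  trad <- vapply(seq_len(400), function(i)
    sample_enjoyment(cohort[i, ], "TRADITIONAL"), integer(1))
  expect_true(all(ga %in% 1:5) && all(trad %in% 1:5))
  expect_gt(mean(ga), mean(trad))
  flat <- make_profile(enjoyment_bias = 0)
  expect_equal(sample_enjoyment(flat, "GAMIFIED"),
               sample_enjoyment(flat, "TRADITIONAL"))
})

test_that("preference shares land at the configured multinomial", {
  prof <- make_profile()
  withr::local_seed(13)
  pref <- vapply(seq_len(1e4), function(i) sample_preference(prof), character(1))
  share_ga <- mean(pref == "GA")
  expect_lt(abs(share_ga - 0.80), 0.02)
  expect_true(all(pref %in% c("GA", "FLANKER", "NONE")))
})

test_that("maximum likelihood recovers generating parameters within 3 SE", {
  prof <- make_profile(lapse = 0, mu = 6.9, sigma = 0.33, delta_incong = 0.22,
                       err_cong = 0.10, err_incong = 0.30, t0_ms = 250)
  withr::local_seed(17)
  n <- 1e4
  congruency <- rep(c("CONGRUENT", "INCONGRUENT"), length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    trial <- list(congruency = congruency[i], target = "LEFT")
    r <- sample_response(prof, trial, Inf)
    tibble::tibble(congruency = congruency[i], rt_ms = r$rt_ms,
                   outcome = classify_response("LEFT", r$response, r$rt_ms, Inf))
  })
  trials <- dplyr::bind_rows(rows)
  fit <- fit_respondent(trials, t0_ms = 250)
  truth <- c(mu = 6.9, sigma = 0.33, delta_incong = 0.22,
             err_cong = 0.10, err_incong = 0.30)
  for (term in names(truth)) {
    row <- fit[fit$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$std_error,
              label = paste("recovery of", term))
  }
})
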