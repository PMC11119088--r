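test_that("paired test agrees with the from-scratch oracle on random samples", {
  withr::local_seed(101)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 5))
    y <- rnorm(n, sd = runif(1, 0.5, 5))
    got <- paired_test(x, y)
    want <- oracle_paired(x, y)
    for (f in c("mean_diff", "sd_diff", "se", "t", "ci95", "cohens_d", "p"))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10)
    # paired d identity
    expect_equal(got$cohens_d, got$t / sqrt(n), tolerance = 1e-12)
    expect_true(got$ci95[1] <= got$mean_diff && got$mean_diff <= got$ci95[2])
  }
})

test_that("identical samples give the degenerate zero result", {
  x <- c(3, 1, 4, 1, 5)
  got <- paired_test(x, x)
  expect_equal(got$t, 0)
  expect_equal(got$cohens_d, 0)
  expect_equal(got$ci95, c(0, 0))
  expect_error(paired_test(1:3, 1:4), class = "flankgame_stat_error")
  expect_error(paired_test(1, 2), class = "flankgame_stat_error")
})

test_that("summary-based paired statistics reproduce printed reports", {
  ga_acc <- paired_from_summary(25.65, 11.71, 20)
  expect_equal(round(ga_acc$t, 2), 9.80)
  expect_equal(round(ga_acc$se, 2), 2.62)
  expect_equal(round(ga_acc$cohens_d, 2), 2.19)
  expect_equal(round(ga_acc$ci95, 2), c(20.17, 31.13))
  ga_rt <- paired_from_summary(389.65, 317.04, 20)
  expect_equal(round(ga_rt$se, 2), 70.89)
  expect_equal(round(ga_rt$t, 2), 5.50)
  null <- paired_from_summary(0, 1, 20)
  expect_equal(null$t, 0)
  expect_equal(null$cohens_d, 0)
  expect_error(paired_from_summary(1, 0, 20), class = "flankgame_stat_error")
  expect_error(paired_from_summary(1, 1, 1), class = "flankgame_stat_error")
})

test_that("pearson correlation matches its oracle and the Fisher interval", {
  withr::local_seed(202)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    got <- pearson_with_ci(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$ci95, want$ci95, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_true(got$ci95[1] >= -1 && got$ci95[2] <= 1)
    expect_true(got$ci95[1] <= got$r && got$r <= got$ci95[2])
  }
  expect_equal(pearson_with_ci(1:10, 2 * (1:10) + 3)$r, 1)
  # the published interval at r = 0.703, n = 20
  z <- atanh(0.703); half <- qnorm(0.975) / sqrt(17)
  expect_equal(round(tanh(c(z - half, z + half)), 2), c(0.38, 0.87))
  expect_error(pearson_with_ci(rep(1, 5), 1:5), class = "flankgame_stat_error")
  expect_error(pearson_with_ci(1:3, 1:3), class = "flankgame_stat_error")
})

test_that("mixed ANOVA matches the cell-means oracle on a small table", {
  withr::local_seed(303)
  for (i in 1:10) {
    n_per <- sample(2:4, 1)
    df <- expand.grid(child = paste0("k", 1:(2 * n_per)),
                      condition = c("A", "B"), stringsAsFactors = FALSE)
    df$order <- ifelse(df$child %in% paste0("k", 1:n_per), "first", "second")
    df$y <- rnorm(nrow(df), mean = 2 * (df$condition == "B"))
    got <- mixed_anova_2x2(df, dv = "y", within = "condition",
                           between = "order", id = "child")
    want <- oracle_mixed_anova(df$y, df$condition, df$order, df$child)
    e <- got$effects
    expect_equal(e$F[e$effect == "order"], want$F_b, tolerance = 1e-10)
    expect_equal(e$F[e$effect == "condition"], want$F_w, tolerance = 1e-10)
    expect_equal(e$F[e$effect == "order:condition"], want$F_bw, tolerance = 1e-10)
    expect_equal(e$partial_eta_sq[e$effect == "order"], want$pes_b, tolerance = 1e-10)
    expect_equal(e$partial_eta_sq[e$effect == "condition"], want$pes_w, tolerance = 1e-10)
    expect_equal(e$partial_eta_sq[e$effect == "order:condition"], want$pes_bw,
                 tolerance = 1e-10)
    expect_equal(e$df1, unname(want$df[c("b", "w", "bw")]))
    expect_true(all(e$partial_eta_sq >= 0 & e$partial_eta_sq <= 1))
  }
})

test_that("mixed ANOVA flags a null within effect and bad designs", {
  df <- expand.grid(child = paste0("k", 1:8), condition = c("A", "B"),
                    stringsAsFactors = FALSE)
  df$order <- ifelse(df$child %in% paste0("k", 1:4), "first", "second")
  withr::local_seed(9)
  base <- rnorm(8)
  df$y <- base[match(df$child, paste0("k", 1:8))] + rnorm(16, sd = 0.1)
  got <- mixed_anova_2x2(df, "y", "condition", "order", "child")
  expect_lt(got$effects$F[got$effects$effect == "condition"], 6)
  expect_error(mixed_anova_2x2(df[-1, ], "y", "condition", "order", "child"),
               class = "flankgame_stat_error")
  df_bad <- df
  df_bad$order[1] <- "second"
  expect_error(mixed_anova_2x2(df_bad, "y", "condition", "order", "child"),
               class = "flankgame_stat_error")
})

test_that("chi-square matches hand computation and its oracle", {
  got <- chi_square_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(got$chi2, 20)
  expect_equal(got$df, 1)
  # proportional rows: exact independence
  prop <- chi_square_independence(matrix(c(10, 20, 5, 20, 40, 10), 2,
                                         byrow = TRUE))
  expect_equal(prop$chi2, 0)
  withr::local_seed(404)
  for (i in 1:20) {
    obs <- matrix(rpois(6, 8) + 1, 2, 3)
    got <- chi_square_independence(obs)
    want <- oracle_chisq(obs)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(rowSums(got$expected), rowSums(obs), tolerance = 1e-10)
    expect_equal(colSums(got$expected), unname(colSums(obs)), tolerance = 1e-10)
  }
  expect_error(chi_square_independence(matrix(c(1, 2, 0, 0), 2)),
               class = "flankgame_stat_error")
  expect_error(chi_square_independence(matrix(1.5, 2, 2)),
               class = "flankgame_stat_error")
})

test_that("confidence intervals tighten as 1/sqrt(n)", {
  a <- paired_from_summary(10, 5, 10)
  b <- paired_from_summary(10, 5, 40)
  expect_equal(a$se / b$se, 2)
})
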