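# Independently coded brute-force oracles. Each reimplements a statistic
# from first principles so the package route is checked against a second,
# structurally different computation.

# paired t from raw differences, pure formulas
oracle_paired <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  se <- s / sqrt(n)
  t <- m / se
  crit <- qt(0.975, n - 1)
  list(mean_diff = m, sd_diff = s, se = se, t = t, df = n - 1,
       ci95 = c(m - crit * se, m + crit * se), cohens_d = m / s,
       p = 2 * pt(-abs(t), n - 1))
}

# Pearson r via raw sums, Fisher-z interval, t-based p
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n
  sy <- y - sum(y) / n
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  z <- 0.5 * log((1 + r) / (1 - r))
  half <- qnorm(0.975) / sqrt(n - 3)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, ci95 = tanh(c(z - half, z + half)),
       p = 2 * pt(-abs(t), n - 2))
}

# Pearson chi-square from the definition
oracle_chisq <- function(obs) {
  obs <- as.matrix(obs)
  E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi2 <- sum((obs - E)^2 / E)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       expected = E)
}

# 2 (between) x 2 (within) mixed ANOVA from cell/marginal means
oracle_mixed_anova <- function(y, w, b, s) {
  w <- factor(w); b <- factor(b); s <- factor(s)
  gm <- mean(y)
  n_w <- nlevels(w)
  subj_means <- tapply(y, s, mean)
  subj_group <- tapply(as.character(b), s, function(v) v[1])
  grp_means <- tapply(y, b, mean)
  n_per_grp <- table(subj_group)

  ss_between_subj <- n_w * sum((subj_means - gm)^2)
  ss_b <- n_w * sum(n_per_grp * (grp_means[names(n_per_grp)] - gm)^2)
  ss_subj_err <- ss_between_subj - ss_b

  w_means <- tapply(y, w, mean)
  n_subj <- nlevels(s)
  ss_w <- n_subj * sum((w_means - gm)^2)
  cell_means <- tapply(y, list(b, w), mean)
  ss_cells <- 0
  for (bi in levels(b)) for (wi in levels(w)) {
    ss_cells <- ss_cells + n_per_grp[[bi]] *
      (cell_means[bi, wi] - grp_means[[bi]] - w_means[[wi]] + gm)^2
  }
  ss_bw <- ss_cells
  ss_total <- sum((y - gm)^2)
  ss_w_err <- ss_total - ss_between_subj - ss_w - ss_bw

  df_b <- nlevels(b) - 1
  df_subj <- n_subj - nlevels(b)
  df_w <- n_w - 1
  df_bw <- df_b * df_w
  df_werr <- df_subj * df_w

  list(
    F_b = (ss_b / df_b) / (ss_subj_err / df_subj),
    F_w = (ss_w / df_w) / (ss_w_err / df_werr),
    F_bw = (ss_bw / df_bw) / (ss_w_err / df_werr),
    pes_b = ss_b / (ss_b + ss_subj_err),
    pes_w = ss_w / (ss_w + ss_w_err),
    pes_bw = ss_bw / (ss_bw + ss_w_err),
    df = c(b = df_b, subj = df_subj, w = df_w, bw = df_bw, werr = df_werr))
}

# staircase endpoint by maximal-run decomposition: split the outcome
# string at errors, count floor(run_length / target) completed streaks
oracle_staircase_final <- function(outcomes, cfg) {
  runs <- rle(outcomes == "CORRECT")
  completed <- sum(floor(runs$lengths[runs$values] / cfg$streak_target))
  max(cfg$floor_ms, cfg$start_window_ms - cfg$step_ms * completed)
}

random_outcomes <- function(n, p_correct = 0.6) {
  ifelse(runif(n) < p_correct, "CORRECT",
         sample(c("COMMISSION", "OMISSION"), n, replace = TRUE))
}

# tiny hand-built trial table for scoring tests
toy_session_trials <- function() {
  tibble::tibble(
    session_id = "s1", child_id = "c1", age_years = 4L,
    condition = "TRADITIONAL", order_position = "FIRST",
    trial_index = 0:5, phase = "TEST", practice_repeat = NA_integer_,
    level_index = NA_integer_,
    congruency = c(rep("CONGRUENT", 4), rep("INCONGRUENT", 2)),
    target = "LEFT",
    window_ms = 1700,
    response = c("LEFT", "LEFT", "LEFT", "NONE", "LEFT", "RIGHT"),
    rt_ms = c(800, 900, 1000, NA, 1200, 700),
    outcome = c("CORRECT", "CORRECT", "CORRECT", "OMISSION",
                "CORRECT", "COMMISSION"),
    feedback = NA_character_, jar_count = NA_integer_, iti_ms = 450)
}
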