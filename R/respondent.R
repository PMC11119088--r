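#' Age-graded respondent parameter presets
#'
#' The generative model for a synthetic child is a shifted lognormal
#' response-time distribution with congruency-specific commission
#' probabilities and a lapse rate: with probability `lapse` the trial is
#' ignored outright; otherwise
#' `RT = t0_ms + exp(mu + delta_incong * [incongruent] + sigma * z)` with
#' `z` standard normal, a response later than the allotted window becomes
#' an omission, and a timely response is wrong with probability
#' `err_cong` / `err_incong`. `slow_gamified` is an additive log-scale
#' slowdown applied in the gamified condition, where the generous opening
#' window removes time pressure.
#'
#' The `"paper2024"` preset was calibrated once, by lognormal tail
#' arithmetic and a confirmation simulation, so that a mixed-age cohort
#' reproduces the feasibility-study profile: a fixed 1700 ms deadline
#' drives 3-year-olds to roughly 23 timeouts out of 42 test trials
#' (about 4 and 1 for 4- and 5-year-olds) and cohort congruent accuracy
#' near 68%, while the adaptive window keeps 3-year-old omissions in the
#' low single digits and congruent accuracy near 88%.
#'
#' @param calibration Preset name; currently `"paper2024"`.
#' @return A tibble with one row per age (3, 4, 5) and the parameter
#'   columns described above.
#' @export
age_presets <- function(calibration = "paper2024") {
  if (!identical(calibration, "paper2024"))
    abort(sprintf("unknown calibration preset '%s'", calibration),
          class = "flankgame_config_error")
  tibble(
    age_years    = c(3L, 4L, 5L),
    t0_ms        = c(250, 250, 250),
    mu           = c(7.25, 6.66, 6.42),
    sigma        = c(0.40, 0.35, 0.32),
    delta_incong = c(0.28, 0.25, 0.22),
    err_cong     = c(0.14, 0.16, 0.13),
    err_incong   = c(0.45, 0.36, 0.25),
    lapse        = c(0.03, 0.02, 0.01),
    slow_gamified = c(0.15, 0.45, 0.50))
}

# Child-level heterogeneity around the age presets and covariate loadings.
# ability_z mixes an age gradient with an individual component; the
# individual component alone perturbs the RT location and error logits so
# the age presets stay interpretable as age means.
COHORT_SHAPE <- list(
  ability_age_loading = 0.75,   # weight of the (standardized) age gradient
  beta_mu = 0.25,               # log-scale RT shift per individual-ability SD
  beta_err = 0.70,              # error logit shift per individual-ability SD
  delta_sd = 0.12,              # between-child spread of the congruency penalty
  covariate_loading = 0.85,     # ability loading of verbal/matrix scores
  enjoy_base_mean = 3.05, enjoy_base_sd = 2.2,
  enjoy_bias_mean = 2.00, enjoy_bias_sd = 0.90,
  preference_probs = c(GA = 0.80, FLANKER = 0.15, NONE = 0.05))

#' Generate a synthetic cohort of child profiles
#'
#' Draws `n` children with ages allocated by largest-remainder rounding of
#' `age_mix`, parameters taken from the age preset and perturbed by a
#' latent ability score, plus synthetic verbal and matrix-reasoning
#' covariates loading on the same ability (WPPSI-style scaled scores,
#' mean 10, SD 3), a latent enjoyment level with a positive gamified
#' shift, and everything needed to act as a responder in [run_session()].
#' Each child draws from a seed-derived sub-stream, so enlarging the
#' cohort never perturbs earlier children.
#'
#' @param n Number of children.
#' @param age_mix Named proportions over ages `"3"`, `"4"`, `"5"`; must
#'   sum to 1. The default 0.3/0.3/0.4 gives the 6/6/8 split at n = 20.
#' @param calibration Preset name passed to [age_presets()].
#' @param seed Integer seed.
#' @return A tibble with one row per child: identifiers, age, all
#'   respondent parameters, `ability_z`, `verbal_score`, `matrix_score`,
#'   `enjoy_base`, `enjoyment_bias`.
#' @examples
#' make_cohort(20, seed = 1)
#' @export
make_cohort <- function(n, age_mix = c("3" = 0.3, "4" = 0.3, "5" = 0.4),
                        calibration = "paper2024", seed = 1L) {
  if (n < 1) abort("n must be at least 1", class = "flankgame_config_error")
  if (!setequal(names(age_mix), c("3", "4", "5")) ||
      abs(sum(age_mix) - 1) > 1e-8)
    abort("age_mix must be proportions over ages 3/4/5 summing to 1",
          class = "flankgame_config_error")
  presets <- age_presets(calibration)
  ages <- rep(c(3L, 4L, 5L), largest_remainder_counts(
    as.numeric(age_mix[c("3", "4", "5")]), n))
  sh <- COHORT_SHAPE
  age_std <- (ages - 4) / stats::sd(c(3, 4, 5))
  rows <- lapply(seq_len(n), function(i) {
    withr::with_seed(child_seed(seed, i), {
      indiv <- rnorm(1)
      ability <- sh$ability_age_loading * age_std[i] +
        sqrt(1 - sh$ability_age_loading^2) * indiv
      p <- presets[presets$age_years == ages[i], ]
      lam <- sh$covariate_loading
      tibble(
        child_id = sprintf("c%03d", i), age_years = ages[i],
        t0_ms = p$t0_ms,
        mu = p$mu - sh$beta_mu * indiv,
        sigma = p$sigma,
        delta_incong = pmax(0, p$delta_incong + sh$delta_sd * rnorm(1)),
        err_cong = stats::plogis(stats::qlogis(p$err_cong) - sh$beta_err * indiv),
        err_incong = stats::plogis(stats::qlogis(p$err_incong) - sh$beta_err * indiv),
        lapse = p$lapse, slow_gamified = p$slow_gamified,
        ability_z = ability,
        verbal_score = 10 + 3 * (lam * ability + sqrt(1 - lam^2) * rnorm(1)),
        matrix_score = 10 + 3 * (lam * ability + sqrt(1 - lam^2) * rnorm(1)),
        enjoy_base = rnorm(1, sh$enjoy_base_mean, sh$enjoy_base_sd),
        enjoyment_bias = rnorm(1, sh$enjoy_bias_mean, sh$enjoy_bias_sd))
    })
  })
  dplyr::bind_rows(rows)
}

largest_remainder_counts <- function(props, n) {
  exact <- props * n
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  as.integer(base)
}

child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 7919 * i) %% 2147483629)
}

#' Sample one trial response from a child profile
#'
#' @param profile One row of a [make_cohort()] tibble.
#' @param trial A one-row schedule data frame (needs `congruency` and
#'   `target`).
#' @param window_ms Allotted response window, ms (may be `Inf`).
#' @param condition `"TRADITIONAL"` or `"GAMIFIED"`; the gamified
#'   condition applies the profile's `slow_gamified` log-scale slowdown.
#' @return `list(response =, rt_ms =)` with `rt_ms = NA` iff no response.
#' @export
sample_response <- function(profile, trial, window_ms,
                            condition = "TRADITIONAL") {
  no_response <- list(response = "NONE", rt_ms = NA_real_)
  if (runif(1) < profile$lapse) return(no_response)
  incong <- trial$congruency == "INCONGRUENT"
  slow <- if (condition == "GAMIFIED") profile$slow_gamified else 0
  rt <- profile$t0_ms +
    rlnorm(1, profile$mu + slow + if (incong) profile$delta_incong else 0,
           profile$sigma)
  if (rt > window_ms) return(no_response)
  err_p <- if (incong) profile$err_incong else profile$err_cong
  response <- if (runif(1) < err_p) opposite_direction(trial$target)
              else trial$target
  list(response = response, rt_ms = rt)
}

opposite_direction <- function(d) if (d == "LEFT") "RIGHT" else "LEFT"

#' Turn a child profile into a responder for [run_session()]
#'
#' @inheritParams sample_response
#' @return A responder closure `(trial, window_ms) -> list(response, rt_ms)`.
#' @export
responder_from_profile <- function(profile, condition = "TRADITIONAL") {
  force(profile); force(condition)
  function(trial, window_ms) sample_response(profile, trial, window_ms, condition)
}

#' Sample enjoyment rating and activity preference
#'
#' The 5-point pictorial (Smileyometer-style) enjoyment rating is a
#' discretized latent: the child's `enjoy_base`, shifted by
#' `enjoyment_bias` in the gamified condition, rounded and clamped to
#' 1..5. The forced-choice preference is multinomial with probabilities
#' 0.80 / 0.15 / 0.05 for the gamified task, the traditional task, and no
#' response.
#'
#' @param profile One row of a [make_cohort()] tibble.
#' @param condition `"TRADITIONAL"` or `"GAMIFIED"`.
#' @return `sample_enjoyment()`: an integer in 1..5.
#'   `sample_preference()`: one of `"GA"`, `"FLANKER"`, `"NONE"`.
#' @export
sample_enjoyment <- function(profile, condition = "TRADITIONAL") {
  latent <- profile$enjoy_base +
    if (condition == "GAMIFIED") profile$enjoyment_bias else 0
  as.integer(pmin(5, pmax(1, round(latent))))
}

#' @rdname sample_enjoyment
#' @export
sample_preference <- function(profile) {
  p <- COHORT_SHAPE$preference_probs
  sample(names(p), 1, prob = p)
}

#' Fit the respondent model to unlimited-window trial data
#'
#' Maximum-likelihood recovery of `(mu, sigma, delta_incong)` from
#' responded-trial RTs (shifted-lognormal likelihood, `t0_ms` known) and
#' closed-form commission-rate estimates per congruency. Intended for
#' checking that simulated data identify their generating parameters.
#'
#' @param trials A tibble with `congruency`, `rt_ms`, `outcome` from
#'   trials run at an effectively unlimited window.
#' @param t0_ms The (known) non-decision time used in generation.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std_error`.
#' @export
fit_respondent <- function(trials, t0_ms) {
  resp <- trials[trials$outcome != "OMISSION" & !is.na(trials$rt_ms), ]
  if (nrow(resp) < 10)
    abort("too few responded trials to fit", class = "flankgame_contract_error")
  x <- log(resp$rt_ms - t0_ms)
  incong <- as.numeric(resp$congruency == "INCONGRUENT")
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2]); delta <- par[3]
    -sum(stats::dnorm(x, mu + delta * incong, sigma, log = TRUE))
  }
  fit <- stats::optim(c(mean(x), log(stats::sd(x)), 0), nll,
                      hessian = TRUE, method = "BFGS")
  vc <- solve(fit$hessian)
  # delta method for sigma = exp(par2)
  est <- c(fit$par[1], exp(fit$par[2]), fit$par[3])
  se <- sqrt(c(vc[1, 1], vc[2, 2] * exp(fit$par[2])^2, vc[3, 3]))
  err_rows <- lapply(c(CONGRUENT = "CONGRUENT", INCONGRUENT = "INCONGRUENT"),
                     function(cls) {
    sub <- resp[resp$congruency == cls, ]
    k <- sum(sub$outcome == "COMMISSION"); m <- nrow(sub)
    phat <- k / m
    tibble(estimate = phat, std_error = sqrt(phat * (1 - phat) / m))
  })
  dplyr::bind_rows(
    tibble(term = c("mu", "sigma", "delta_incong"),
           estimate = est, std_error = se),
    tibble(term = c("err_cong", "err_incong"),
           estimate = c(err_rows$CONGRUENT$estimate, err_rows$INCONGRUENT$estimate),
           std_error = c(err_rows$CONGRUENT$std_error, err_rows$INCONGRUENT$std_error)))
}
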