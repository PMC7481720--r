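# Monte-Carlo power and sensitivity estimation for the omnibus model.
#
# Each replicate draws a participant-level dataset from the configured
# design (gender ratio, correlated 5-level income/education, outcome =
# X beta + normal error), fits the full-interaction OLS once, and evaluates
# every registered test (a coefficient or simple-effect contrast) two-sided
# at alpha. Power for a test is the proportion of replicates with p < alpha
# (strict).

#' Calibrate the residual SD to the pilot standard errors
#'
#' The analyses standardize D, so the generating model's error SD is not
#' printed anywhere; it is instead pinned down by the printed pilot standard
#' errors. This function finds the sigma for which the expected standard
#' error of the Gender x Income coefficient at the pilot design (n = 175,
#' 115:60 women:men, observed income-education r = 0.22) equals the printed
#' value of 0.055. The expected design moment matrix `E[x x']` is
#' approximated once by a large fixed-seed draw from the design distribution
#' and cached for the session.
#'
#' @param target_se Printed pilot s.e. of the Gender x Income coefficient.
#' @param n_pilot Pilot analysis sample size.
#' @param prop_women Pilot proportion of women.
#' @param income_education_corr Observed income-education correlation.
#' @param n_mc Monte-Carlo size for the design-moment approximation.
#' @return Calibrated residual SD (scalar).
#' @examples
#' calibrate_residual_sd()  # about 0.34
#' @export
calibrate_residual_sd <- function(target_se = 0.055, n_pilot = 175,
                                  prop_women = 115 / 175,
                                  income_education_corr = 0.22,
                                  n_mc = 200000) {
  key <- paste(target_se, n_pilot, prop_women, income_education_corr, n_mc,
               sep = "|")
  cached <- .iatpower_cache$residual_sd
  if (!is.null(cached) && identical(cached$key, key)) return(cached$value)
  M <- design_moments(prop_women, income_education_corr, n_mc)
  unit_se <- sqrt(solve(M)["gender_income", "gender_income"] / n_pilot)
  value <- target_se / unit_se
  .iatpower_cache$residual_sd <- list(key = key, value = value)
  value
}

# E[x x'] of the omnibus design row, by a fixed-seed draw so calibration is
# deterministic and independent of user seeds
design_moments <- function(prop_women, income_education_corr, n_mc,
                           income_marginals = pilot_marginals()$income,
                           education_marginals = pilot_marginals()$education) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(191232L)
  X <- draw_design(n_mc, prop_women, income_education_corr,
                   income_marginals, education_marginals,
                   sample_standardize = FALSE)
  M <- crossprod(X) / n_mc
  dimnames(M) <- list(OMNIBUS_TERMS, OMNIBUS_TERMS)
  M
}

# one design draw: gender +-0.5, discretized correlated income/education
# z-scored either within-sample (analysis convention) or against the
# marginal population moments
draw_design <- function(n, prop_women, income_education_corr,
                        income_marginals, education_marginals,
                        sample_standardize = TRUE) {
  g <- ifelse(runif(n) < prop_women, -0.5, 0.5)
  rl <- latent_correlation(income_education_corr, income_marginals,
                           education_marginals)
  z1 <- rnorm(n)
  z2 <- rl * z1 + sqrt(1 - rl^2) * rnorm(n)
  inc <- cut_latent(z1, income_marginals)
  edu <- cut_latent(z2, education_marginals)
  if (sample_standardize) {
    iz <- standardize(inc)
    ez <- standardize(edu)
  } else {
    iz <- ordinal_z(inc, income_marginals)
    ez <- ordinal_z(edu, education_marginals)
  }
  cbind(intercept = 1, gender = g, income = iz, education = ez,
        gender_income = g * iz, gender_education = g * ez,
        income_education = iz * ez, gender_income_education = g * iz * ez)
}

#' Configuration for a power simulation
#'
#' Defaults reproduce the stage-1 projected-power conditions: 1000
#' simulated datasets of 1000 participants each, pilot gender ratio,
#' observed income-education correlation 0.22, the reconstructed pilot
#' coefficient vector, residual SD calibrated to the pilot standard errors,
#' and alpha = 0.05. Set `n_per_dataset = 767` for the stage-2 (observed
#' final sample) conditions.
#'
#' @param n_per_dataset Participants per simulated dataset.
#' @param n_reps Number of simulated datasets.
#' @param alpha Two-sided significance level.
#' @param coef_vector Generating coefficients (named, length 8).
#' @param residual_sd Error SD; `NULL` uses [calibrate_residual_sd()].
#' @param prop_women Proportion of women.
#' @param income_education_corr Observed income-education correlation.
#' @param income_marginals,education_marginals Ordinal level probabilities.
#' @param tests Named list of test specifications (as in
#'   [default_simple_effects()]); defaults to the full battery.
#' @param sample_standardize_predictors z-score income/education within each
#'   simulated sample (analysis convention; default TRUE).
#' @param standardize_outcome Re-standardize the simulated outcome within
#'   each dataset (default FALSE; two-sided t statistics, hence power, are
#'   invariant to this choice, and FALSE keeps the coefficient scale equal
#'   to the generating scale).
#' @param seed Master seed (mandatory). Per-rep seeds are pre-drawn from it
#'   so replicates are independently reproducible.
#' @return Object of class `power_config`.
#' @export
power_config <- function(n_per_dataset = 1000, n_reps = 1000, alpha = 0.05,
                         coef_vector = pilot_coef_vector(),
                         residual_sd = NULL,
                         prop_women = 115 / 175,
                         income_education_corr = 0.22,
                         income_marginals = pilot_marginals()$income,
                         education_marginals = pilot_marginals()$education,
                         tests = default_simple_effects(),
                         sample_standardize_predictors = TRUE,
                         standardize_outcome = FALSE,
                         seed) {
  if (missing(seed))
    iat_stop("`seed` is mandatory in a power_config", "iatpower_validation_error")
  check_scalar(seed, "seed")
  check_scalar(n_per_dataset, "n_per_dataset", lower = 20)
  check_scalar(n_reps, "n_reps", lower = 1)
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_proportion(prop_women, "prop_women")
  check_scalar(income_education_corr, "income_education_corr", lower = -1,
               upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  coef_vector <- check_coef_vector(coef_vector)
  if (is.null(residual_sd)) residual_sd <- calibrate_residual_sd()
  check_scalar(residual_sd, "residual_sd", lower = 0, strict_lower = TRUE)
  if (!length(tests) || is.null(names(tests)) || any(!nzchar(names(tests))))
    iat_stop("`tests` must be a non-empty named list", "iatpower_validation_error")
  structure(list(n_per_dataset = as.integer(n_per_dataset),
                 n_reps = as.integer(n_reps), alpha = alpha,
                 coef_vector = coef_vector, residual_sd = residual_sd,
                 prop_women = prop_women,
                 income_education_corr = income_education_corr,
                 income_marginals = income_marginals,
                 education_marginals = education_marginals,
                 tests = tests,
                 sample_standardize_predictors = sample_standardize_predictors,
                 standardize_outcome = standardize_outcome,
                 seed = as.integer(seed)),
            class = "power_config")
}

#' Simulate one analysis-ready dataset
#'
#' @param config A [power_config()].
#' @param rep_seed Seed for this replicate.
#' @return Data.frame with `gender` (+-0.5), `income_z`, `education_z`,
#'   `d_z` (outcome).
#' @export
simulate_dataset <- function(config, rep_seed) {
  set.seed(rep_seed)
  X <- draw_design(config$n_per_dataset, config$prop_women,
                   config$income_education_corr, config$income_marginals,
                   config$education_marginals,
                   sample_standardize = config$sample_standardize_predictors)
  y <- as.numeric(X %*% config$coef_vector) +
    rnorm(config$n_per_dataset, 0, config$residual_sd)
  if (config$standardize_outcome) y <- standardize(y)
  data.frame(gender = X[, "gender"], income_z = X[, "income"],
             education_z = X[, "education"], d_z = y)
}

# fast OLS + contrast tests for one replicate; returns p-values per test
fit_and_test <- function(X, y, contrasts, dfres) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NULL)
  b <- qr.coef(qx, y)
  res <- y - as.numeric(X %*% b)
  sigma2 <- sum(res^2) / dfres
  XtXinv <- chol2inv(qr.R(qx))
  vapply(contrasts, function(cv) {
    est <- sum(cv * b)
    se <- sqrt(drop(t(cv) %*% XtXinv %*% cv) * sigma2)
    2 * pt(-abs(est / se), dfres)
  }, numeric(1))
}

#' Estimate power by Monte-Carlo simulation
#'
#' @param config A [power_config()].
#' @param effect_multiplier Multiplier applied to selected generating
#'   coefficients before simulating (used by [sensitivity()]; 1 for main
#'   runs). Either a scalar applied to all non-intercept terms or a named
#'   vector over terms.
#' @return Object of class `power_result`: data.frame with one row per
#'   test -- `test`, `power`, `mc_se` (binomial SE), `n_significant`,
#'   `n_reps`, `n`, `alpha`, `effect_multiplier` -- with the number of
#'   redrawn singular replicates in attribute `n_redrawn`.
#' @examples
#' cfg <- power_config(n_per_dataset = 200, n_reps = 50, seed = 42,
#'                     tests = list(gi = list(effect = "gender_by_income")))
#' estimate_power(cfg)
#' @export
estimate_power <- function(config, effect_multiplier = 1) {
  if (!inherits(config, "power_config"))
    iat_stop("`config` must be a power_config", "iatpower_validation_error")
  beta <- config$coef_vector
  if (!is.null(names(effect_multiplier))) {
    bad <- setdiff(names(effect_multiplier), OMNIBUS_TERMS)
    if (length(bad))
      iat_stop(paste("unknown coefficient in effect_multiplier:",
                     paste(bad, collapse = ", ")), "iatpower_validation_error")
    beta[names(effect_multiplier)] <-
      beta[names(effect_multiplier)] * effect_multiplier
  } else if (!identical(effect_multiplier, 1)) {
    beta[-1] <- beta[-1] * effect_multiplier
  }
  sim_config <- config
  sim_config$coef_vector <- beta

  contrasts <- lapply(config$tests, function(ef) {
    contrast_vector(ef$effect, gender = ef$gender,
                    income_z = ef$income_z %||% 0,
                    education_z = ef$education_z %||% 0)
  })
  dfres <- config$n_per_dataset - 8L

  # per-rep seeds pre-drawn from the master seed (counter scheme: the first
  # n_reps entries are the replicate seeds, the tail is a redraw pool)
  set.seed(config$seed)
  pool <- sample.int(.Machine$integer.max - 1L, config$n_reps + 200L)
  rep_seeds <- pool[seq_len(config$n_reps)]
  redraw_pool <- pool[-seq_len(config$n_reps)]

  n_sig <- integer(length(contrasts))
  n_redrawn <- 0L
  next_redraw <- 1L
  for (r in seq_len(config$n_reps)) {
    seed_r <- rep_seeds[r]
    repeat {
      dat <- simulate_dataset(sim_config, seed_r)
      X <- cbind(1, dat$gender, dat$income_z, dat$education_z,
                 dat$gender * dat$income_z, dat$gender * dat$education_z,
                 dat$income_z * dat$education_z,
                 dat$gender * dat$income_z * dat$education_z)
      pvals <- fit_and_test(X, dat$d_z, contrasts, dfres)
      if (!is.null(pvals)) break
      n_redrawn <- n_redrawn + 1L
      seed_r <- redraw_pool[next_redraw]
      next_redraw <- next_redraw + 1L
      if (next_redraw > length(redraw_pool))
        iat_stop("too many singular replicates", "iatpower_degenerate_error")
    }
    n_sig <- n_sig + (pvals < config$alpha)
  }

  power <- n_sig / config$n_reps
  out <- data.frame(test = names(config$tests), power = power,
                    mc_se = sqrt(power * (1 - power) / config$n_reps),
                    n_significant = n_sig, n_reps = config$n_reps,
                    n = config$n_per_dataset, alpha = config$alpha,
                    effect_multiplier = if (is.null(names(effect_multiplier)))
                      effect_multiplier else NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_redrawn") <- n_redrawn
  class(out) <- c("power_result", "data.frame")
  out
}

#' Sensitivity analysis: power under shrunken effect sizes
#'
#' Re-runs the power simulation with one generating coefficient multiplied
#' by `1 - shrink` for each shrink factor, reporting the power curve for the
#' test of that coefficient and the largest shrink that keeps power at or
#' above `power_target`. The same master seed (hence the same replicate
#' seeds) is used at every grid point, so the curve uses common random
#' numbers.
#'
#' @param config A [power_config()].
#' @param target_test Name of the coefficient to shrink (e.g.
#'   `"gender_income_education"` for the three-way interaction).
#' @param shrink_factors Grid of shrink proportions in `[0, 1]`.
#' @param power_target Power criterion (default 0.80).
#' @return List with `curve` (data.frame: shrink, effect_multiplier, power,
#'   mc_se) and `max_shrink_at_target` (largest shrink with power >=
#'   `power_target`, or `NA`).
#' @export
sensitivity <- function(config, target_test = "gender_income_education",
                        shrink_factors = seq(0, 0.5, by = 0.1),
                        power_target = 0.80) {
  if (!target_test %in% OMNIBUS_TERMS[-1])
    iat_stop("`target_test` must name a non-intercept coefficient",
             "iatpower_validation_error")
  if (any(shrink_factors < 0 | shrink_factors > 1))
    iat_stop("shrink factors must lie in [0, 1]", "iatpower_validation_error")
  test_effect <- switch(target_test,
    gender = list(effect = "gender_main"),
    income = list(effect = "income_main"),
    education = list(effect = "education_main"),
    gender_income = list(effect = "gender_by_income"),
    gender_education = list(effect = "gender_by_education"),
    income_education = list(effect = "income_by_education"),
    gender_income_education = list(effect = "three_way"))
  cfg <- config
  cfg$tests <- setNames(list(test_effect), target_test)
  rows <- lapply(shrink_factors, function(s) {
    mult <- setNames(1 - s, target_test)
    pr <- estimate_power(cfg, effect_multiplier = mult)
    data.frame(shrink = s, effect_multiplier = 1 - s, power = pr$power,
               mc_se = pr$mc_se, n_reps = pr$n_reps, n = pr$n)
  })
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  ok <- curve$shrink[curve$power >= power_target]
  list(curve = curve,
       max_shrink_at_target = if (length(ok)) max(ok) else NA_real_,
       power_target = power_target)
}
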