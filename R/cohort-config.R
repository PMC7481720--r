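#' Configuration for a synthetic participant cohort
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' Defaults reproduce the pilot study conditions: n = 175 with a 115:60
#' women:men ratio, an observed income-education correlation of 0.22, and
#' group-level D differences following the pilot regression coefficients.
#'
#' @param n_participants Positive integer, number of participants.
#' @param prop_women Proportion of women in `[0, 1]`.
#' @param income_education_corr Target observed (post-discretization)
#'   correlation between the 5-level income and education scales, strictly
#'   inside (-1, 1).
#' @param coef_vector Named length-8 vector of generating regression weights
#'   on standardized scales (see [pilot_coef_vector()] for names and
#'   defaults).
#' @param residual_sd Positive residual standard deviation of the true D
#'   around the linear predictor. `NULL` (default) uses
#'   [calibrate_residual_sd()], which matches the pilot standard error of the
#'   Gender x Income coefficient (0.055 at n = 175).
#' @param careless_rate Proportion of participants assigned a careless
#'   responding archetype (fast-responder, high-error or ultra-slow).
#' @param missing_income_rate,missing_education_rate Proportions of
#'   participants with a missing (or "I don't know") income / a missing
#'   education response.
#' @param income_marginals,education_marginals Length-5 probability vectors
#'   for the ordinal levels 1-5; defaults are the pilot marginals.
#' @param seed Integer random seed (mandatory).
#'
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_participants = 50, seed = 1)
#' @export
cohort_config <- function(n_participants = 175,
                          prop_women = 115 / 175,
                          income_education_corr = 0.22,
                          coef_vector = pilot_coef_vector(),
                          residual_sd = NULL,
                          careless_rate = 0,
                          missing_income_rate = 0,
                          missing_education_rate = 0,
                          income_marginals = pilot_marginals()$income,
                          education_marginals = pilot_marginals()$education,
                          seed) {
  if (missing(seed))
    iat_stop("`seed` is mandatory in a cohort_config", "iatpower_validation_error")
  check_scalar(seed, "seed")
  check_scalar(n_participants, "n_participants", lower = 1)
  if (n_participants != round(n_participants))
    iat_stop("`n_participants` must be an integer", "iatpower_validation_error")
  check_proportion(prop_women, "prop_women")
  check_scalar(income_education_corr, "income_education_corr",
               lower = -1, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_proportion(careless_rate, "careless_rate")
  check_proportion(missing_income_rate, "missing_income_rate")
  check_proportion(missing_education_rate, "missing_education_rate")
  coef_vector <- check_coef_vector(coef_vector)
  if (is.null(residual_sd)) residual_sd <- calibrate_residual_sd()
  check_scalar(residual_sd, "residual_sd", lower = 0, strict_lower = TRUE)
  for (nm in c("income_marginals", "education_marginals")) {
    p <- get(nm)
    if (!is.numeric(p) || length(p) != 5L || any(!is.finite(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8)
      iat_stop(sprintf("`%s` must be 5 probabilities summing to 1", nm),
               "iatpower_validation_error")
  }
  structure(list(n_participants = as.integer(n_participants),
                 prop_women = prop_women,
                 income_education_corr = income_education_corr,
                 coef_vector = coef_vector,
                 residual_sd = residual_sd,
                 careless_rate = careless_rate,
                 missing_income_rate = missing_income_rate,
                 missing_education_rate = missing_education_rate,
                 income_marginals = income_marginals,
                 education_marginals = education_marginals,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

check_coef_vector <- function(coef_vector) {
  if (!is.numeric(coef_vector) || length(coef_vector) != 8L ||
      any(!is.finite(coef_vector)))
    iat_stop("`coef_vector` must be 8 finite regression weights",
             "iatpower_validation_error")
  if (is.null(names(coef_vector))) {
    names(coef_vector) <- OMNIBUS_TERMS
  } else if (!setequal(names(coef_vector), OMNIBUS_TERMS)) {
    iat_stop(paste0("`coef_vector` names must be: ",
                    paste(OMNIBUS_TERMS, collapse = ", ")),
             "iatpower_validation_error")
  }
  coef_vector[OMNIBUS_TERMS]
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d (prop women %.3f), income-education r = %.2f\n",
              x$n_participants, x$prop_women, x$income_education_corr))
  cat(sprintf("  residual SD = %.4f, careless rate = %.2f, seed = %d\n",
              x$residual_sd, x$careless_rate, x$seed))
  cat("  coefficients:\n")
  print(round(x$coef_vector, 4))
  invisible(x)
}

#' Response-latency model for synthetic IAT trials
#'
#' Latencies are lognormal, truncated below at 150 ms and rounded to integer
#' milliseconds. The incompatible pairing (poor + good for a pro-rich
#' participant) receives an additive shift on the log scale; larger shifts
#' produce larger expected D scores.
#'
#' @param log_mean_base Location of log-latency (log ms); default `log(700)`.
#' @param log_sd Scale of log-latency (> 0).
#' @param incompatible_shift Additive log-ms shift applied to the
#'   incompatible pairing; controls the true D.
#' @param error_prob_base,error_prob_incompatible Error probabilities for the
#'   compatible / incompatible pairing, in `[0, 1]`.
#'
#' @return An object of class `latency_model`.
#' @examples
#' latency_model(incompatible_shift = 0.2)
#' @export
latency_model <- function(log_mean_base = log(700),
                          log_sd = 0.35,
                          incompatible_shift = 0.15,
                          error_prob_base = 0.05,
                          error_prob_incompatible = 0.08) {
  check_scalar(log_mean_base, "log_mean_base")
  check_scalar(log_sd, "log_sd", lower = 0, strict_lower = TRUE)
  check_scalar(incompatible_shift, "incompatible_shift")
  check_proportion(error_prob_base, "error_prob_base")
  check_proportion(error_prob_incompatible, "error_prob_incompatible")
  structure(list(log_mean_base = log_mean_base, log_sd = log_sd,
                 incompatible_shift = incompatible_shift,
                 error_prob_base = error_prob_base,
                 error_prob_incompatible = error_prob_incompatible),
            class = "latency_model")
}

#' Expected D score implied by a latency model
#'
#' Closed-form approximation (ignoring the 150 ms truncation and error
#' replacement): for lognormal latencies with scale `log_sd` and a log-shift
#' `delta` on the incompatible blocks, the expected block-mean difference and
#' pooled SD follow from lognormal moments of the two-component mixture.
#'
#' @param model A [latency_model()].
#' @param shift Optional shift overriding `model$incompatible_shift`.
#' @return Approximate expected D (unitless).
#' @export
expected_d <- function(model, shift = model$incompatible_shift) {
  s2 <- model$log_sd^2
  m1 <- exp(model$log_mean_base + s2 / 2)
  m2 <- m1 * exp(shift)
  v1 <- m1^2 * (exp(s2) - 1)
  v2 <- m2^2 * (exp(s2) - 1)
  pooled_var <- (v1 + v2) / 2 + (m2 - m1)^2 / 4
  (m2 - m1) / sqrt(pooled_var)
}

#' Log-latency shift producing a target D
#'
#' Numerically inverts [expected_d()] so the cohort generator can give each
#' participant a trial-level latency structure whose expected scored D equals
#' the participant's model-implied true D.
#'
#' @param model A [latency_model()].
#' @param d_target Finite target D score.
#' @return The log-ms shift.
#' @export
shift_for_d <- function(model, d_target) {
  check_scalar(d_target, "d_target", lower = -1.9, upper = 1.9)
  if (d_target == 0) return(0)
  stats::uniroot(function(delta) expected_d(model, delta) - d_target,
                 lower = -5, upper = 5, tol = 1e-10)$root
}
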