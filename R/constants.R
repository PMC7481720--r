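# Design constants shared across modules.
#
# Block layout of the 7-block evaluative IAT: blocks 1, 2 and 5 are
# single-task introductory/transition blocks; blocks 3 and 6 are 20-trial
# dual-categorization practice blocks; blocks 4 and 7 are 40-trial critical
# blocks. Only blocks 3, 4, 6, 7 enter D scoring.
IAT_BLOCK_SIZES <- c(`1` = 20L, `2` = 20L, `3` = 20L, `4` = 40L,
                     `5` = 20L, `6` = 20L, `7` = 40L)
IAT_PRACTICE_BLOCKS <- c(3L, 6L)
IAT_CRITICAL_BLOCKS <- c(4L, 7L)
IAT_SCORED_BLOCKS <- c(3L, 4L, 6L, 7L)

# Scoring constants: trials slower than 10 000 ms are dropped (strictly
# "exceeding", so exactly 10 000 ms is retained); error latencies are
# replaced by the block's correct-trial mean plus a 600 ms penalty.
LATENCY_CAP_MS <- 10000
ERROR_PENALTY_MS <- 600
FAST_CUTOFF_MS <- 300

# Participant-level exclusion thresholds (percent), compared with >= at the
# printed values using exact integer arithmetic.
EXCLUSION_THRESHOLDS <- c(c1 = 35, c2 = 25, c3 = 10, c4 = 50,
                          c5 = 40, c6 = 40, c7 = 30, c8 = 10)

#' Pilot-sample regression coefficient vector
#'
#' The default generating coefficients for the synthetic cohort and the power
#' engine, on standardized scales with gender contrast-coded
#' women = -0.5 / men = +0.5. The vector is reconstructed from the pilot
#' omnibus model and its simple-effect decomposition: with this coding the
#' Gender x Income coefficient equals the difference between the men's and
#' women's income slopes, the gender coefficient equals the gender difference
#' at mean income, and the education coefficient equals the average of the
#' four education simple slopes, so the pilot estimates pin the vector down
#' to rounding error (see the methods vignette).
#'
#' @return Named numeric vector of length 8 with names `intercept`, `gender`,
#'   `income`, `education`, `gender_income`, `gender_education`,
#'   `income_education`, `gender_income_education`.
#' @examples
#' pilot_coef_vector()
#' @export
pilot_coef_vector <- function() {
  c(intercept = 0,
    gender = 0.084,
    income = 0.040,
    education = 0.111,
    gender_income = 0.132,
    gender_education = 0.0455,
    income_education = -0.036,
    gender_income_education = -0.089)
}

#' Pilot marginal distributions of income and education
#'
#' Marginal frequencies of the 5-level income and education scales in the
#' pilot analysis sample (n = 175), used to discretize the latent bivariate
#' normal in the synthetic cohort generator.
#'
#' @return A list with components `income` and `education`, each a numeric
#'   vector of 5 proportions summing to 1, and `prop_women` (115/175).
#' @export
pilot_marginals <- function() {
  list(income = c(35, 42, 39, 42, 17) / 175,
       education = c(2, 11, 54, 71, 37) / 175,
       prop_women = 115 / 175)
}

# canonical term names of the omnibus design, in model order
OMNIBUS_TERMS <- c("intercept", "gender", "income", "education",
                   "gender_income", "gender_education", "income_education",
                   "gender_income_education")

# internal condition helper: classed errors so callers/tests can
# discriminate validation failures from degenerate-input failures
iat_stop <- function(msg, class) {
  stop(structure(class = c(class, "iatpower_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    iat_stop(sprintf("`%s` must be a single finite proportion in [0, 1], got %s",
                     name, deparse(x)), "iatpower_validation_error")
  invisible(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok)
    iat_stop(sprintf("`%s` must be a single finite number in %s%s, %s%s, got %s",
                     name, if (strict_lower) "(" else "[", lower, upper,
                     if (strict_upper) ")" else "]", deparse(x)),
             "iatpower_validation_error")
  invisible(x)
}
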