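# Omnibus Gender x Income x Education moderated regression on standardized
# IAT D scores, with per-predictor variance-inflation diagnostics, the
# pre-registered orthogonalization contingency, and simple-effect
# decomposition as linear combinations of the omnibus coefficients.
#
# Gender is contrast-coded women = -0.5, men = +0.5. With that coding the
# Gender x Income coefficient equals the men-minus-women difference in
# income slopes, and the gender coefficient equals the gender difference at
# the mean of income and education, which is exactly the pattern of the
# pilot estimates.

GENDER_CODE <- c(f = -0.5, m = 0.5)

#' z-transform a numeric vector
#'
#' Centered at the sample mean and scaled by the sample SD (n - 1), as
#' applied to income, education and the D score on the analysis sample after
#' all exclusions.
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @return z-scores (mean 0, sample SD 1).
#' @examples
#' standardize(1:5)
#' @export
standardize <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L)
    iat_stop("cannot z-transform: fewer than 2 distinct values (zero variance)",
             "iatpower_degenerate_error")
  (values - mean(v)) / sd(v)
}

# classical column-wise VIF: diagonal of the inverse correlation matrix of
# the non-intercept design columns
design_vif <- function(X) {
  R <- cor(X)
  diag(solve(R))
}

as_gender_code <- function(gender) {
  if (is.numeric(gender)) {
    if (!all(gender %in% c(-0.5, 0.5)))
      iat_stop("numeric gender must be coded -0.5 (women) / +0.5 (men)",
               "iatpower_validation_error")
    return(gender)
  }
  g <- as.character(gender)
  key <- ifelse(g %in% c("f", "woman", "women", "female"), "f",
                ifelse(g %in% c("m", "man", "men", "male"), "m", NA))
  if (anyNA(key))
    iat_stop("gender must be f/m (or woman/man)", "iatpower_validation_error")
  unname(GENDER_CODE[key])
}

#' Fit the omnibus moderated regression
#'
#' Ordinary least squares of the outcome on
#' `{1, G, I, E, GI, GE, IE, GIE}` where G is contrast-coded gender and
#' I, E are z-scored income and education. Per-predictor VIFs are computed
#' for the seven non-intercept columns; if any exceeds `vif_threshold` the
#' pre-registered contingency is applied: income is residualized on
#' education and the model refit (the refit's VIFs are reported alongside a
#' flag).
#'
#' @param data Data.frame with columns `gender` (f/m or numeric +-0.5) and
#'   the outcome / predictor columns named below.
#' @param outcome,income,education Column names (defaults `"d_z"`,
#'   `"income_z"`, `"education_z"`).
#' @param vif_threshold Threshold for the orthogonalization contingency
#'   (default 10).
#' @return Object of class `iat_omnibus`: list with `coefficients` (a
#'   data.frame: term, b, se, ci_low, ci_high, t, df, p, vif), `beta`
#'   (named vector in canonical term order), `vcov`, `df_residual`, `n`,
#'   `vif`, `orthogonalized`, and the underlying `lm` fit.
#' @examples
#' set.seed(1)
#' d <- data.frame(gender = sample(c("f", "m"), 60, TRUE),
#'                 income_z = rnorm(60), education_z = rnorm(60))
#' d$d_z <- 0.3 * d$income_z + rnorm(60)
#' fit_omnibus(d)
#' @export
fit_omnibus <- function(data, outcome = "d_z", income = "income_z",
                        education = "education_z", vif_threshold = 10) {
  need <- c("gender", outcome, income, education)
  if (!all(need %in% names(data)))
    iat_stop(paste("`data` must have columns:", paste(need, collapse = ", ")),
             "iatpower_validation_error")
  df <- data.frame(Y = data[[outcome]], G = as_gender_code(data$gender),
                   I = data[[income]], E = data[[education]])
  df <- df[complete.cases(df), ]
  if (nrow(df) < 20L)
    iat_stop("need at least 20 complete cases", "iatpower_validation_error")
  if (length(unique(df$G)) < 2L)
    iat_stop("both genders must be present", "iatpower_validation_error")

  fit_once <- function(df) {
    m <- lm(Y ~ G * I * E, data = df)
    if (any(is.na(coef(m)))) {
      bad <- names(coef(m))[is.na(coef(m))]
      iat_stop(paste("rank-deficient design; collinear term(s):",
                     paste(bad, collapse = ", ")),
               "iatpower_degenerate_error")
    }
    m
  }
  m <- fit_once(df)
  X <- stats::model.matrix(m)[, -1]
  vif <- design_vif(X)
  orthogonalized <- FALSE
  if (any(vif > vif_threshold)) {
    # pre-registered contingency: keep the income variance independent of
    # education, then rebuild the interactions from the residualized income
    df$I <- resid(lm(I ~ E, data = df))
    m <- fit_once(df)
    X <- stats::model.matrix(m)[, -1]
    vif <- design_vif(X)
    orthogonalized <- TRUE
  }

  n <- nrow(df)
  dfres <- n - 8L
  sm <- summary(m)$coefficients
  b <- sm[, 1]; se <- sm[, 2]; tval <- sm[, 3]
  p <- 2 * pt(-abs(tval), dfres)
  tcrit <- qt(0.975, dfres)
  lm_terms <- c("(Intercept)", "G", "I", "E", "G:I", "G:E", "I:E", "G:I:E")
  ord <- match(lm_terms, rownames(sm))
  coefs <- data.frame(term = OMNIBUS_TERMS, b = b[ord], se = se[ord],
                      ci_low = (b - tcrit * se)[ord],
                      ci_high = (b + tcrit * se)[ord],
                      t = tval[ord], df = dfres, p = p[ord],
                      vif = c(NA, vif[match(lm_terms[-1], names(vif))]),
                      row.names = NULL, stringsAsFactors = FALSE)
  beta <- setNames(coefs$b, OMNIBUS_TERMS)
  V <- vcov(m)[lm_terms, lm_terms]
  dimnames(V) <- list(OMNIBUS_TERMS, OMNIBUS_TERMS)
  structure(list(coefficients = coefs, beta = beta, vcov = V,
                 df_residual = dfres, n = n,
                 vif = setNames(coefs$vif[-1], OMNIBUS_TERMS[-1]),
                 orthogonalized = orthogonalized, lm_fit = m),
            class = "iat_omnibus")
}

#' @export
print.iat_omnibus <- function(x, ...) {
  cat(sprintf("Omnibus Gender x Income x Education model (n = %d, df = %d%s)\n",
              x$n, x$df_residual,
              if (x$orthogonalized) ", income orthogonalized" else ""))
  print(transform(x$coefficients,
                  b = round(b, 4), se = round(se, 4), ci_low = round(ci_low, 4),
                  ci_high = round(ci_high, 4), t = round(t, 3),
                  p = signif(p, 3), vif = round(vif, 2)))
  invisible(x)
}

#' Contrast vector for a simple effect
#'
#' Returns the length-8 weight vector c (in canonical term order) such that
#' the requested simple effect equals `c %*% beta` for the omnibus model
#' with gender coded women = -0.5 / men = +0.5.
#'
#' Supported effects: `income_slope` (per gender, at an education point),
#' `education_slope` (per gender, at an income point), `gender_difference`
#' (men minus women, at income/education points), `gender_by_income` (at an
#' education point), `gender_by_education` (at an income point),
#' `income_by_education` (per gender), `education_main` / `income_main`
#' (slope at gender midpoint 0), `gender_main`, and `three_way`.
#'
#' @param effect Effect name.
#' @param gender `"f"`/`"m"` (or +-0.5) where the effect is gender-specific.
#' @param income_z,education_z Moderator evaluation points in z units
#'   (e.g. +-1.5 for the follow-up models).
#' @return Named numeric vector of length 8.
#' @examples
#' # men's income slope = income + 0.5 * gender_income
#' contrast_vector("income_slope", gender = "m")
#' @export
contrast_vector <- function(effect, gender = NULL, income_z = 0,
                            education_z = 0) {
  z <- setNames(numeric(8), OMNIBUS_TERMS)
  g <- if (!is.null(gender)) as_gender_code(gender) else NULL
  needs_gender <- function() {
    if (is.null(g)) iat_stop(sprintf("effect `%s` needs a `gender`", effect),
                             "iatpower_validation_error")
    g
  }
  switch(effect,
    income_slope = {
      g <- needs_gender()
      z[c("income", "gender_income", "income_education",
          "gender_income_education")] <-
        c(1, g, education_z, g * education_z)
    },
    education_slope = {
      g <- needs_gender()
      z[c("education", "gender_education", "income_education",
          "gender_income_education")] <-
        c(1, g, income_z, g * income_z)
    },
    gender_difference = ,
    gender_main = {
      z[c("gender", "gender_income", "gender_education",
          "gender_income_education")] <-
        c(1, income_z, education_z, income_z * education_z)
    },
    gender_by_income = {
      z[c("gender_income", "gender_income_education")] <- c(1, education_z)
    },
    gender_by_education = {
      z[c("gender_education", "gender_income_education")] <- c(1, income_z)
    },
    income_by_education = {
      # gender defaults to the contrast midpoint 0 (the IE coefficient)
      if (is.null(g)) g <- 0
      z[c("income_education", "gender_income_education")] <- c(1, g)
    },
    income_main = {
      z[c("income", "income_education")] <- c(1, education_z)
    },
    education_main = {
      z[c("education", "income_education")] <- c(1, income_z)
    },
    three_way = {
      z["gender_income_education"] <- 1
    },
    iat_stop(sprintf("effect `%s` is outside the supported simple-effect family",
                     effect), "iatpower_validation_error")
  )
  z
}

#' Estimate simple effects from a fitted omnibus model
#'
#' Each requested effect is an exact linear combination `c %*% beta` with
#' standard error `sqrt(c' Sigma c)`; degrees of freedom are the omnibus
#' residual df, so the estimates are identical to re-centering the
#' predictors and refitting.
#'
#' @param fit An `iat_omnibus` object.
#' @param effects A named list; each element a list with `effect` and
#'   optional `gender`, `income_z`, `education_z` (see [contrast_vector()]).
#'   Defaults to the full decomposition battery used for the power analyses
#'   ([default_simple_effects()]).
#' @return Data.frame: `name`, `effect`, `gender`, `income_z`,
#'   `education_z`, `b`, `se`, `ci_low`, `ci_high`, `t`, `df`, `p`.
#' @examples
#' set.seed(2)
#' d <- data.frame(gender = rep(c("f", "m"), 50),
#'                 income_z = rnorm(100), education_z = rnorm(100))
#' d$d_z <- 0.2 * d$income_z * (d$gender == "m") + rnorm(100)
#' simple_effects(fit_omnibus(d))
#' @export
simple_effects <- function(fit, effects = default_simple_effects()) {
  if (!inherits(fit, "iat_omnibus"))
    iat_stop("`fit` must be an iat_omnibus object", "iatpower_validation_error")
  rows <- lapply(names(effects), function(nm) {
    ef <- effects[[nm]]
    cv <- contrast_vector(ef$effect, gender = ef$gender,
                          income_z = ef$income_z %||% 0,
                          education_z = ef$education_z %||% 0)
    est <- sum(cv * fit$beta)
    se <- sqrt(drop(t(cv) %*% fit$vcov %*% cv))
    tval <- est / se
    tcrit <- qt(0.975, fit$df_residual)
    data.frame(name = nm, effect = ef$effect,
               gender = ef$gender %||% NA_character_,
               income_z = ef$income_z %||% 0,
               education_z = ef$education_z %||% 0,
               b = est, se = se, ci_low = est - tcrit * se,
               ci_high = est + tcrit * se, t = tval, df = fit$df_residual,
               p = 2 * pt(-abs(tval), fit$df_residual),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default simple-effect battery
#'
#' The decomposition reported for the pilot model and powered in the
#' simulations: the two-way and three-way interactions, income slopes per
#' gender, education slopes per gender at income -1.5/+1.5 s.d., gender
#' differences at income -1.5/0/+1.5 s.d., the Gender x Education
#' interaction at income +-1.5 s.d., and the education main effect at
#' income +1.5 s.d.
#'
#' @return Named list of effect specifications for [simple_effects()].
#' @export
default_simple_effects <- function() {
  list(
    gender_by_income = list(effect = "gender_by_income"),
    three_way = list(effect = "three_way"),
    income_slope_men = list(effect = "income_slope", gender = "m"),
    income_slope_women = list(effect = "income_slope", gender = "f"),
    gender_diff_high_income = list(effect = "gender_difference", income_z = 1.5),
    gender_diff_mean_income = list(effect = "gender_difference"),
    gender_diff_low_income = list(effect = "gender_difference", income_z = -1.5),
    gender_by_education_low_income = list(effect = "gender_by_education",
                                          income_z = -1.5),
    gender_by_education_high_income = list(effect = "gender_by_education",
                                           income_z = 1.5),
    education_slope_women_low_income = list(effect = "education_slope",
                                            gender = "f", income_z = -1.5),
    education_slope_men_low_income = list(effect = "education_slope",
                                          gender = "m", income_z = -1.5),
    education_slope_women_high_income = list(effect = "education_slope",
                                             gender = "f", income_z = 1.5),
    education_slope_men_high_income = list(effect = "education_slope",
                                           gender = "m", income_z = 1.5),
    education_main_high_income = list(effect = "education_main", income_z = 1.5),
    education_main = list(effect = "education_main")
  )
}
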