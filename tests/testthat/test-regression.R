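# Moderated regression: standardization, exact recovery, the
# normal-equations oracle, VIF behaviour and the orthogonalization
# contingency, and the simple-effect linear-combination identities
# (including the pilot-consistency suite).

test_that("standardize gives mean 0 / sample SD 1 and rejects constants", {
  z <- standardize(c(1, 2, 3, 4, 5))
  expect_equal(mean(z), 0, tolerance = 1e-14)
  expect_equal(sd(z), 1, tolerance = 1e-14)
  expect_error(standardize(rep(3, 10)), class = "iatpower_degenerate_error")
})

make_design <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(gender = sample(c("f", "m"), n, TRUE),
             income_z = rnorm(n), education_z = rnorm(n))
}

lp_from <- function(d, beta) {
  g <- ifelse(d$gender == "m", 0.5, -0.5)
  X <- cbind(1, g, d$income_z, d$education_z, g * d$income_z,
             g * d$education_z, d$income_z * d$education_z,
             g * d$income_z * d$education_z)
  as.numeric(X %*% beta)
}

test_that("noise-free data reproduce the generating coefficients exactly", {
  beta <- pilot_coef_vector()
  d <- make_design(60, seed = 2)
  d$d_z <- lp_from(d, beta)
  fit <- fit_omnibus(d)
  expect_equal(unname(fit$beta), unname(beta), tolerance = 1e-10)
  expect_identical(fit$df_residual, 52L)
})

test_that("an orthogonal balanced design has all VIF equal to 1", {
  d <- expand.grid(gender = c("f", "m"), income_z = c(-1, 1),
                   education_z = c(-1, 1))
  d <- d[rep(seq_len(nrow(d)), 3), ]
  d$gender <- as.character(d$gender)
  set.seed(3)
  d$d_z <- rnorm(nrow(d))
  fit <- fit_omnibus(d)
  expect_equal(unname(fit$vif), rep(1, 7), tolerance = 1e-10)
})

test_that("coefficients and standard errors match the normal-equations oracle", {
  beta <- pilot_coef_vector()
  d <- make_design(24, seed = 4)
  set.seed(5)
  d$d_z <- lp_from(d, beta) + rnorm(24, 0, 0.4)
  fit <- fit_omnibus(d)
  g <- ifelse(d$gender == "m", 0.5, -0.5)
  X <- cbind(1, g, d$income_z, d$education_z, g * d$income_z,
             g * d$education_z, d$income_z * d$education_z,
             g * d$income_z * d$education_z)
  b_hat <- solve(t(X) %*% X) %*% t(X) %*% d$d_z
  res <- d$d_z - X %*% b_hat
  s2 <- sum(res^2) / (24 - 8)
  se_hat <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(unname(fit$beta), as.numeric(b_hat), tolerance = 1e-10)
  expect_equal(fit$coefficients$se, unname(se_hat), tolerance = 1e-10)
})

test_that("severe income-education collinearity triggers the residualization contingency", {
  set.seed(6)
  n <- 80
  e <- rnorm(n)
  d <- data.frame(gender = sample(c("f", "m"), n, TRUE),
                  education_z = e, income_z = e + rnorm(n, 0, 0.02))
  d$d_z <- rnorm(n)
  fit <- fit_omnibus(d)
  expect_true(fit$orthogonalized)
  expect_true(all(fit$vif[c("income", "education")] < 10))
  # mild correlation (pilot-like 0.22) never triggers it
  d2 <- make_design(120, seed = 7)
  d2$income_z <- 0.22 * d2$education_z + sqrt(1 - 0.22^2) * rnorm(120)
  d2$d_z <- rnorm(120)
  expect_false(fit_omnibus(d2)$orthogonalized)
})

test_that("degenerate designs raise informative errors", {
  d <- make_design(30, seed = 8)
  d$d_z <- rnorm(30)
  d$gender <- "f"
  expect_error(fit_omnibus(d), "gender", class = "iatpower_validation_error")
  d2 <- make_design(10, seed = 9)
  d2$d_z <- rnorm(10)
  expect_error(fit_omnibus(d2), "20", class = "iatpower_validation_error")
})

test_that("simple effects are exact linear combinations of the omnibus fit", {
  beta <- pilot_coef_vector()
  d <- make_design(200, seed = 10)
  set.seed(11)
  d$d_z <- lp_from(d, beta) + rnorm(200, 0, 0.3)
  fit <- fit_omnibus(d)
  se <- simple_effects(fit)
  b <- fit$beta
  row <- function(nm) se[se$name == nm, ]
  # slope-difference identity: men minus women income slopes = the GI term
  expect_equal(row("income_slope_men")$b - row("income_slope_women")$b,
               unname(b["gender_income"]), tolerance = 1e-12)
  # gender difference at mean income/education = the gender term
  expect_equal(row("gender_diff_mean_income")$b, unname(b["gender"]),
               tolerance = 1e-12)
  # average of the four education slopes at +-1.5 s.d. income = education term
  avg_edu <- mean(c(row("education_slope_women_low_income")$b,
                    row("education_slope_men_low_income")$b,
                    row("education_slope_women_high_income")$b,
                    row("education_slope_men_high_income")$b))
  expect_equal(avg_edu, unname(b["education"]), tolerance = 1e-12)
})

test_that("simple effects equal re-centred refits to within 1e-10", {
  d <- make_design(150, seed = 12)
  set.seed(13)
  d$d_z <- lp_from(d, pilot_coef_vector()) + rnorm(150, 0, 0.3)
  fit <- fit_omnibus(d)
  target <- simple_effects(fit, list(
    men_high = list(effect = "education_slope", gender = "m", income_z = 1.5)))
  # re-centre: shift income so +1.5 s.d. is the origin, gender so men are 0
  g <- ifelse(d$gender == "m", 0.5, -0.5)
  refit <- lm(d_z ~ G * I * E,
              data = data.frame(d_z = d$d_z, G = g - 0.5,
                                I = d$income_z - 1.5, E = d$education_z))
  sm <- summary(refit)$coefficients
  expect_equal(target$b, sm["E", 1], tolerance = 1e-10)
  expect_equal(target$se, sm["E", 2], tolerance = 1e-10)
})

test_that("the reconstructed vector reproduces all ten printed pilot simple effects", {
  beta <- pilot_coef_vector()
  tab <- pilot_simple_effects_table()
  for (i in seq_len(nrow(tab))) {
    cv <- contrast_vector(tab$effect[i],
                          gender = if (is.na(tab$gender[i])) NULL else tab$gender[i],
                          income_z = tab$income_z[i])
    expect_lt(abs(sum(cv * beta) - tab$printed[i]), 0.002)
  }
  # the omnibus-level prints: education main at high income and GE there
  expect_lt(abs(sum(contrast_vector("education_main", income_z = 1.5) * beta) -
                  0.058), 0.002)
  expect_lt(abs(sum(contrast_vector("gender_by_education", income_z = 1.5) * beta) -
                  (-0.089)), 0.002)
})

test_that("unsupported simple-effect requests are rejected", {
  expect_error(contrast_vector("quadratic_income"),
               class = "iatpower_validation_error")
  expect_error(contrast_vector("income_slope"), "gender",
               class = "iatpower_validation_error")
})
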