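# Synthetic cohort generator: demographic structure, the
# binormal-then-discretize correlation target, IAT trial structure and the
# latency-shift / D calibration, explicit-item offsets, and determinism.

test_that("config validation rejects out-of-range parameters by name", {
  expect_error(cohort_config(seed = 1, prop_women = 1.2), "prop_women",
               class = "iatpower_validation_error")
  expect_error(cohort_config(seed = 1, income_education_corr = 1),
               "income_education_corr", class = "iatpower_validation_error")
  expect_error(cohort_config(seed = 1, careless_rate = -0.1), "careless_rate",
               class = "iatpower_validation_error")
  expect_error(cohort_config(n_participants = 10), "seed",
               class = "iatpower_validation_error")
  expect_error(cohort_config(seed = 1, coef_vector = rep(0, 3)),
               class = "iatpower_validation_error")
})

test_that("demographics match the configured gender ratio and missingness", {
  cfg <- cohort_config(n_participants = 2000, seed = 11,
                       missing_income_rate = 0.15,
                       missing_education_rate = 0.05)
  demo <- generate_demographics(cfg)
  expect_identical(nrow(demo), 2000L)
  expect_false(any(duplicated(demo$participant_id)))
  p_w <- mean(demo$gender == "f")
  expect_lt(abs(p_w - 115 / 175), 4 * sqrt(115 / 175 * 60 / 175 / 2000))
  # binomial 99.99% bands for the missingness rates
  expect_lt(abs(mean(is.na(demo$income_level)) - 0.15),
            4 * sqrt(0.15 * 0.85 / 2000))
  expect_lt(abs(mean(is.na(demo$education_level)) - 0.05),
            4 * sqrt(0.05 * 0.95 / 2000))
  # timestamps strictly increasing by participant order
  ts <- as.POSIXct(demo$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  expect_true(all(diff(as.numeric(ts)) > 0))
})

test_that("observed income-education correlation hits the target after discretization", {
  cfg <- cohort_config(n_participants = 10000, income_education_corr = 0.22,
                       seed = 12)
  demo <- generate_demographics(cfg)
  r <- cor(demo$income_level, demo$education_level)
  expect_lt(abs(r - 0.22), 0.03)

  cfg0 <- cohort_config(n_participants = 4000, income_education_corr = 0,
                        seed = 13)
  d0 <- generate_demographics(cfg0)
  # 99.9% band: |r| under independence is approx N(0, 1/sqrt(n))
  expect_lt(abs(cor(d0$income_level, d0$education_level)), 3.3 / sqrt(4000))
})

test_that("trial tables have the 7-block structure with pairing-coded counterbalancing", {
  tr <- generate_iat_trials("P1", latency_model(), 0.4, seed = 21,
                            order_condition = "incongruent_first")
  expect_identical(as.integer(table(tr$block)),
                   as.integer(c(20, 20, 20, 40, 20, 20, 40)))
  expect_true(all(tr$latency_ms >= 150))
  expect_true(all(tr$error %in% 0:1))
  expect_identical(unique(tr$pairing[tr$block %in% c(1, 2, 5)]), "single_task")
  # incongruent first: blocks 3/4 carry the poor+good pairing
  expect_identical(unique(tr$pairing[tr$block %in% c(3, 4)]), "poor_good")
  expect_identical(unique(tr$pairing[tr$block %in% c(6, 7)]), "rich_good")
})

test_that("the fast-responder archetype trips criterion 1 downstream", {
  tr <- generate_iat_trials("P1", latency_model(), 0, seed = 22,
                            archetype = "fast_responder")
  rep <- apply_iat_criteria(tr)
  expect_true(rep$c1)
  expect_gte(rep$max_fast_prop_practice, 0.35)
  slow <- generate_iat_trials("P2", latency_model(), 0, seed = 23,
                              archetype = "ultra_slow")
  expect_true(apply_iat_criteria(slow)$c8)
  errs <- generate_iat_trials("P3", latency_model(), 0, seed = 24,
                              archetype = "high_error")
  expect_true(apply_iat_criteria(errs)$c7)
})

test_that("mean scored D is near zero without a shift and increases with it", {
  model0 <- latency_model(incompatible_shift = 0, error_prob_base = 0,
                          error_prob_incompatible = 0)
  grid <- c(0, 0.1, 0.25)
  n_per <- 120
  d0 <- vapply(seq_len(n_per), function(i) {
    tr <- generate_iat_trials(
      "x", model0, 0, seed = 5000 + i,
      order_condition = if (i %% 2) "congruent_first" else "incongruent_first")
    score_iat(tr)$d
  }, numeric(1))
  expect_lt(abs(mean(d0)), 0.05)  # symmetric latencies, no shift

  means_shift <- vapply(seq_along(grid), function(k) {
    target <- expected_d(model0, grid[k])
    d <- vapply(seq_len(n_per), function(i) {
      tr <- generate_iat_trials(
        "x", model0, target, seed = 9000 * k + i,
        order_condition = if (i %% 2) "congruent_first" else "incongruent_first")
      score_iat(tr)$d
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(means_shift) > 0))  # strictly increasing in shift
  # and the realized means track the analytic calibration target
  targets <- vapply(grid, function(s) expected_d(model0, s), numeric(1))
  expect_lt(max(abs(means_shift - targets)), 0.08)
})

test_that("counterbalanced order leaves the expected D unchanged", {
  model0 <- latency_model(error_prob_base = 0, error_prob_incompatible = 0)
  d_by_order <- vapply(c("congruent_first", "incongruent_first"), function(oc) {
    mean(vapply(1:100, function(i) {
      score_iat(generate_iat_trials("x", model0, 0.4,
                                    seed = i + 300 * nchar(oc),
                                    order_condition = oc))$d
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(d_by_order[1] - d_by_order[2]), 0.08)
  expect_true(all(d_by_order > 0.25))
})

test_that("an explicit-measure offset is recovered from the generated items", {
  off <- default_explicit_offsets()
  off[["1"]] <- 0.7
  vals <- vapply(1:700, function(i) {
    m <- build_measures(generate_explicit_items("x", seed = i, offsets = off,
                                                measure_codes = 1L))
    m$value[m$measure_code == 1L]
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.7), 0.1)
})

test_that("regenerating with the same seed is byte-identical", {
  cfg <- cohort_config(n_participants = 15, seed = 77, careless_rate = 0.2,
                       missing_income_rate = 0.1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  dir.create(f1); dir.create(f2)
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(unname(tools::md5sum(file.path(f1, "trials.csv"))),
                   unname(tools::md5sum(file.path(f2, "trials.csv"))))
})

test_that("cohort true D follows the configured coefficient vector", {
  # women/men split with a strong gender effect only
  beta <- c(intercept = 0, gender = 0.5, income = 0, education = 0,
            gender_income = 0, gender_education = 0, income_education = 0,
            gender_income_education = 0)
  cfg <- cohort_config(n_participants = 400, seed = 31, coef_vector = beta,
                       residual_sd = 0.05)
  coh <- generate_cohort(cfg)
  men <- coh$demographics$gender == "m"
  gap <- mean(coh$truth$true_d[men]) - mean(coh$truth$true_d[!men])
  expect_lt(abs(gap - 0.5), 0.05)
})
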