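# synthetic cohort generator: demographics, trial-level IAT data, explicit
# item ratings. Emulates the structure of the AIID rich-poor evaluative IAT
# arm so every downstream stage can be exercised without the archived data.

#' Hermite attenuation factor of a discretized standard normal
#'
#' Correlation between a latent standard normal and its 5-level
#' discretization at the quantile cutpoints of `marginals`:
#' `E[f(X) X] / sd(f(X))` with `E[f(X) X] = sum_k k (phi(a_{k-1}) - phi(a_k))`.
#' Used to inflate the latent income-education correlation so the observed
#' (post-discretization) correlation matches the configured value.
#'
#' @param marginals Length-5 probability vector.
#' @return Attenuation factor in (0, 1].
#' @keywords internal
discretization_attenuation <- function(marginals) {
  a <- qnorm(cumsum(marginals))          # upper cutpoints, last = Inf
  al <- c(-Inf, a[-5])
  k <- 1:5
  e_fx_x <- sum(k * (dnorm(al) - dnorm(a)))
  mu <- sum(k * marginals)
  sdf <- sqrt(sum(k^2 * marginals) - mu^2)
  e_fx_x / sdf
}

#' Latent correlation needed for a target observed correlation
#'
#' First-order (Hermite) correction for the attenuation caused by cutting a
#' bivariate normal into two 5-level ordinal scales. At the magnitudes used
#' here (r around 0.22) higher-order terms are negligible; the unit tests
#' confirm the observed correlation by simulation.
#'
#' @param target_corr Desired observed correlation between the two ordinal
#'   variables.
#' @param income_marginals,education_marginals Level probabilities.
#' @return Latent correlation to use in the bivariate normal.
#' @export
latent_correlation <- function(target_corr,
                               income_marginals = pilot_marginals()$income,
                               education_marginals = pilot_marginals()$education) {
  lam <- discretization_attenuation(income_marginals) *
    discretization_attenuation(education_marginals)
  r <- target_corr / lam
  if (abs(r) >= 1)
    iat_stop("target correlation not attainable after discretization",
             "iatpower_validation_error")
  r
}

cut_latent <- function(z, marginals) {
  cuts <- c(-Inf, qnorm(cumsum(marginals))[1:4], Inf)
  as.integer(cut(z, cuts, labels = FALSE))
}

#' Generate participant demographics
#'
#' Draws gender (women `"f"` / men `"m"`), 5-level income and education with
#' a configured observed correlation, missingness at the configured rates,
#' unique participant IDs and strictly increasing ISO-8601 timestamps.
#' Income missingness also stands in for the "I don't know" response option,
#' which the analysis treats identically.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with columns `participant_id`, `gender`,
#'   `income_level`, `education_level` (integer 1-5 or `NA`), `timestamp`.
#' @examples
#' demo <- generate_demographics(cohort_config(n_participants = 20, seed = 1))
#' @export
generate_demographics <- function(config) {
  if (!inherits(config, "cohort_config"))
    iat_stop("`config` must be a cohort_config", "iatpower_validation_error")
  n <- config$n_participants
  set.seed(config$seed)
  gender <- ifelse(runif(n) < config$prop_women, "f", "m")
  rl <- latent_correlation(config$income_education_corr,
                           config$income_marginals, config$education_marginals)
  z1 <- rnorm(n)
  z2 <- rl * z1 + sqrt(1 - rl^2) * rnorm(n)
  income <- cut_latent(z1, config$income_marginals)
  education <- cut_latent(z2, config$education_marginals)
  income[runif(n) < config$missing_income_rate] <- NA_integer_
  education[runif(n) < config$missing_education_rate] <- NA_integer_
  data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    gender = gender,
    income_level = income,
    education_level = education,
    timestamp = format(as.POSIXct("2019-06-01 08:00:00", tz = "UTC") +
                         60 * seq_len(n), "%Y-%m-%dT%H:%M:%SZ"),
    stringsAsFactors = FALSE
  )
}

# one block of trials for one participant; the (possibly negative) log-shift
# goes on the poor+good pairing, so positive shift => slower poor+good =>
# positive scored D (pro-rich), and the expected D is antisymmetric in shift
simulate_block <- function(block, n_trials, pairing, model, shift) {
  incompatible <- pairing == "poor_good"
  mu <- model$log_mean_base + if (incompatible) shift else 0
  err_p <- if (incompatible) model$error_prob_incompatible else model$error_prob_base
  lat <- as.integer(round(pmax(150, rlnorm(n_trials, mu, model$log_sd))))
  data.frame(block = block,
             trial_index = seq_len(n_trials),
             latency_ms = lat,
             error = as.integer(runif(n_trials) < err_p),
             pairing = pairing,
             stringsAsFactors = FALSE)
}

#' Generate the 7-block IAT trial sequence for one participant
#'
#' Emits blocks 1-7 (introductory/transition blocks 1, 2, 5; 20-trial
#' dual-categorization practice blocks 3, 6; 40-trial critical blocks 4, 7)
#' with lognormal latencies truncated at 150 ms, error flags, and the pairing
#' role (`rich_good` / `poor_good` / `single_task`) recorded independently of
#' presentation order. Block order is counterbalanced via `order_condition`.
#'
#' Careless-responding archetypes replace portions of the data so each
#' participant-level exclusion criterion has a dedicated fixture:
#' `"fast_responder"` makes >= 35% of one practice block faster than 300 ms
#' (criterion 1), `"high_error"` raises the pooled critical-block error rate
#' above 30% (criterion 7), `"ultra_slow"` pushes >= 10% of critical-block
#' trials beyond 10 000 ms (criterion 8).
#'
#' @param participant_id Identifier copied onto every trial.
#' @param model A [latency_model()].
#' @param true_d_target Finite target D; translated into a log-latency shift
#'   via [shift_for_d()].
#' @param seed Integer seed.
#' @param order_condition `"congruent_first"` (blocks 3/4 are rich+good) or
#'   `"incongruent_first"`.
#' @param attribute_set 1 or 2, the attribute word-set condition.
#' @param archetype `"none"` or one of the careless archetypes above.
#' @return A data.frame of trials (schema of `trials.csv`).
#' @examples
#' tr <- generate_iat_trials("P1", latency_model(), 0.4, seed = 2)
#' table(tr$block)
#' @export
generate_iat_trials <- function(participant_id, model = latency_model(),
                                true_d_target = 0, seed,
                                order_condition = c("congruent_first",
                                                    "incongruent_first"),
                                attribute_set = 1L,
                                archetype = c("none", "fast_responder",
                                              "high_error", "ultra_slow")) {
  check_scalar(true_d_target, "true_d_target", lower = -1.9, upper = 1.9)
  order_condition <- match.arg(order_condition)
  archetype <- match.arg(archetype)
  if (!attribute_set %in% c(1L, 2L))
    iat_stop("`attribute_set` must be 1 or 2", "iatpower_validation_error")
  set.seed(seed)
  shift <- shift_for_d(model, true_d_target)
  first_pair <- if (order_condition == "congruent_first") "rich_good" else "poor_good"
  second_pair <- setdiff(c("rich_good", "poor_good"), first_pair)
  pairings <- c(`1` = "single_task", `2` = "single_task",
                `3` = first_pair, `4` = first_pair,
                `5` = "single_task",
                `6` = second_pair, `7` = second_pair)
  out <- do.call(rbind, lapply(1:7, function(b) {
    simulate_block(b, IAT_BLOCK_SIZES[[as.character(b)]],
                   pairings[[as.character(b)]], model, shift)
  }))
  out <- apply_archetype(out, archetype)
  data.frame(participant_id = participant_id, out,
             order_condition = order_condition,
             attribute_set = as.integer(attribute_set),
             stringsAsFactors = FALSE)
}

apply_archetype <- function(trials, archetype) {
  if (archetype == "none") return(trials)
  crit <- trials$block %in% IAT_CRITICAL_BLOCKS
  if (archetype == "fast_responder") {
    # 40% of block 3 under 300 ms (>= 35% threshold of criterion 1)
    idx <- which(trials$block == 3L)
    k <- ceiling(0.40 * length(idx))
    trials$latency_ms[idx[seq_len(k)]] <-
      as.integer(round(runif(k, 150, 290)))
  } else if (archetype == "high_error") {
    # pooled critical-block error rate 50% (>= 30% threshold of criterion 7)
    idx <- which(crit)
    k <- ceiling(0.50 * length(idx))
    trials$error[idx] <- 0L
    trials$error[sample(idx, k)] <- 1L
  } else if (archetype == "ultra_slow") {
    # 15% of critical trials over 10 000 ms (>= 10% threshold of criterion 8)
    idx <- which(crit)
    k <- ceiling(0.15 * length(idx))
    trials$latency_ms[sample(idx, k)] <-
      as.integer(round(runif(k, 10500, 14000)))
  }
  trials
}

# scale metadata for explicit measures 1-14 (15-18 exist in the item pool but
# are never analysed). `targets`: whether items are asked separately for the
# rich and the poor or once about both ("both" = bipolar or polarity items).
EXPLICIT_MEASURES <- list(
  list(code = 1L,  label = "personal evaluations",      lo = 1, hi = 10, targets = "each", n_items = 1L),
  list(code = 2L,  label = "others' evaluations",       lo = -3, hi = 3, targets = "both", n_items = 3L),
  list(code = 3L,  label = "cultural evaluations",      lo = 1, hi = 10, targets = "each", n_items = 1L),
  list(code = 4L,  label = "internal pressure",         lo = 1, hi = 6,  targets = "each", n_items = 1L),
  list(code = 5L,  label = "others' pressure",          lo = 1, hi = 6,  targets = "each", n_items = 2L),
  list(code = 6L,  label = "cultural pressure",         lo = 1, hi = 6,  targets = "each", n_items = 2L),
  list(code = 7L,  label = "monopolar positive",        lo = 1, hi = 6,  targets = "each", n_items = 1L),
  list(code = 8L,  label = "monopolar negative",        lo = 1, hi = 6,  targets = "each", n_items = 1L),
  list(code = 9L,  label = "relative personal preference", lo = -3, hi = 3, targets = "both", n_items = 1L),
  list(code = 10L, label = "gut reactions",             lo = 1, hi = 10, targets = "each", n_items = 1L),
  list(code = 11L, label = "actual feelings",           lo = 1, hi = 10, targets = "each", n_items = 1L),
  list(code = 12L, label = "polarity",                  lo = 1, hi = 6,  targets = "both", n_items = 2L),
  list(code = 13L, label = "identity",                  lo = 1, hi = 6,  targets = "each", n_items = 1L),
  list(code = 14L, label = "self-concept centrality",   lo = 1, hi = 6,  targets = "each", n_items = 1L)
)

#' Default rich-minus-poor mean offsets for the explicit generator
#'
#' Raw-scale offsets (rich mean minus poor mean, before any reverse-coding)
#' loosely following the pilot descriptives: a modest explicit pro-rich tilt
#' on personal measures and a perceived pro-poor tilt for others'/cultural
#' evaluations.
#'
#' @return Named numeric vector indexed by measure code.
#' @export
default_explicit_offsets <- function() {
  c(`1` = 0.7, `2` = 1.0, `3` = -3.0, `4` = 0.7, `5` = -0.15, `6` = 0,
    `7` = 0.3, `8` = -0.3, `9` = 0, `10` = 0.3, `11` = 0.6, `12` = 0,
    `13` = 0.05, `14` = 0.9)
}

draw_rating <- function(n, lo, hi, mean_shift = 0, sd = 1.4) {
  mid <- (lo + hi) / 2
  pmin(hi, pmax(lo, round(rnorm(n, mid + mean_shift, sd))))
}

#' Generate item-level explicit ratings for one participant
#'
#' Produces the item-level responses behind explicit measures 1-14 on their
#' documented scales (1-10 evaluations, -3..3 bipolar preference, 1-6
#' agreement and monopolar ratings), with configurable rich-versus-poor mean
#' offsets. For bipolar ("both"-target) measures the offset shifts the single
#' rating; for separate rich/poor items it is split evenly between targets.
#'
#' @param participant_id Identifier.
#' @param seed Integer seed.
#' @param offsets Named offsets per measure code, see
#'   [default_explicit_offsets()].
#' @param measure_codes Which measures to emit (default all of 1-14).
#' @return A data.frame with columns `participant_id`, `measure_code`,
#'   `item_code`, `target` (`rich`/`poor`/`both`), `response`.
#' @export
generate_explicit_items <- function(participant_id, seed,
                                    offsets = default_explicit_offsets(),
                                    measure_codes = 1:14) {
  set.seed(seed)
  rows <- lapply(EXPLICIT_MEASURES, function(m) {
    if (!m$code %in% measure_codes) return(NULL)
    off <- offsets[[as.character(m$code)]]
    if (is.null(off) || is.na(off)) off <- 0
    if (m$targets == "both") {
      data.frame(participant_id = participant_id, measure_code = m$code,
                 item_code = sprintf("m%02d_i%d", m$code, seq_len(m$n_items)),
                 target = "both",
                 response = draw_rating(m$n_items, m$lo, m$hi, off),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(c(rich = +1, poor = -1), function(sgn) {
        tgt <- if (sgn > 0) "rich" else "poor"
        data.frame(participant_id = participant_id, measure_code = m$code,
                   item_code = sprintf("m%02d_%s_i%d", m$code, tgt,
                                       seq_len(m$n_items)),
                   target = tgt,
                   response = draw_rating(m$n_items, m$lo, m$hi, sgn * off / 2),
                   stringsAsFactors = FALSE)
      }))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic cohort
#'
#' Chains demographics, true-D assignment from the configured coefficient
#' vector, trial-level IAT data and explicit items. True D for participant i
#' is `x_i' beta + e_i` with `e_i ~ N(0, residual_sd)`, where the design row
#' uses gender coded women = -0.5 / men = +0.5 and income/education z-scored
#' against their configured marginal distributions (so participants with a
#' missing demographic still receive a D). Counterbalancing, the attribute
#' word-set split (approx. 9:1), and careless archetypes are assigned per
#' participant.
#'
#' @param config A [cohort_config()].
#' @param model A [latency_model()].
#' @param duplicate_ids Optional character vector of participant IDs to emit
#'   a second, later-timestamped demographic record for (deduplication
#'   fixtures).
#' @return List with data.frames `demographics`, `trials`, `explicit` and
#'   `truth` (per-participant true D, archetype, linear predictor).
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 8, seed = 3))
#' names(coh)
#' @export
generate_cohort <- function(config, model = latency_model(),
                            duplicate_ids = NULL) {
  demo <- generate_demographics(config)
  n <- nrow(demo)
  set.seed(config$seed + 1L)

  g <- ifelse(demo$gender == "m", 0.5, -0.5)
  iz <- ordinal_z(demo$income_level, config$income_marginals)
  ez <- ordinal_z(demo$education_level, config$education_marginals)
  X <- cbind(1, g, iz, ez, g * iz, g * ez, iz * ez, g * iz * ez)
  lp <- as.numeric(X %*% config$coef_vector)
  true_d <- lp + rnorm(n, 0, config$residual_sd)
  true_d <- pmin(1.8, pmax(-1.8, true_d))

  archetype <- rep("none", n)
  n_careless <- round(config$careless_rate * n)
  if (n_careless > 0) {
    idx <- sample.int(n, n_careless)
    archetype[idx] <- sample(c("fast_responder", "high_error", "ultra_slow"),
                             n_careless, replace = TRUE)
  }
  order_condition <- ifelse(runif(n) < 0.5, "congruent_first",
                            "incongruent_first")
  attribute_set <- ifelse(runif(n) < 157 / 175, 1L, 2L)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n)
  item_seeds <- sample.int(.Machine$integer.max - 1L, n)

  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    generate_iat_trials(demo$participant_id[i], model, true_d[i],
                        seed = trial_seeds[i],
                        order_condition = order_condition[i],
                        attribute_set = attribute_set[i],
                        archetype = archetype[i])
  }))
  explicit <- do.call(rbind, lapply(seq_len(n), function(i) {
    generate_explicit_items(demo$participant_id[i], seed = item_seeds[i])
  }))
  rownames(trials) <- rownames(explicit) <- NULL

  if (!is.null(duplicate_ids)) {
    dup <- demo[demo$participant_id %in% duplicate_ids, , drop = FALSE]
    if (nrow(dup)) {
      dup$timestamp <- format(
        as.POSIXct(dup$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC") +
          86400, "%Y-%m-%dT%H:%M:%SZ")
      demo <- rbind(demo, dup)
    }
  }

  list(demographics = demo,
       trials = trials,
       explicit = explicit,
       truth = data.frame(participant_id = sprintf("P%05d", seq_len(n)),
                          true_d = true_d, linear_predictor = lp,
                          archetype = archetype, stringsAsFactors = FALSE))
}

# z-score ordinal levels against the marginal distribution they were drawn
# from (population standardization; NA stays NA but contributes 0 to the
# linear predictor via zero-imputation at generation time)
ordinal_z <- function(levels_1_5, marginals) {
  mu <- sum((1:5) * marginals)
  sdv <- sqrt(sum((1:5)^2 * marginals) - mu^2)
  z <- (levels_1_5 - mu) / sdv
  z[is.na(z)] <- 0
  z
}

#' Write the three cohort tables as CSV
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             demographics = file.path(dir, "demographics.csv"),
             explicit = file.path(dir, "explicit.csv"))
  write.csv(cohort$trials, paths[["trials"]], row.names = FALSE)
  write.csv(cohort$demographics, paths[["demographics"]], row.names = FALSE)
  write.csv(cohort$explicit, paths[["explicit"]], row.names = FALSE)
  invisible(paths)
}
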