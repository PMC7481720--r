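# Independent, deliberately naive re-implementation of the 9-step D-score
# procedure, written as a literal transcription with loops. Kept separate
# from the package path so it can serve as an oracle.
naive_d_score <- function(trials) {
  keep <- trials$block %in% c(3, 4, 6, 7) & trials$latency_ms <= 10000
  tr <- trials[keep, ]
  blocks <- c(3, 4, 6, 7)
  correct_mean <- c()
  for (b in blocks) {
    v <- c()
    for (i in seq_len(nrow(tr)))
      if (tr$block[i] == b && tr$error[i] == 0) v <- c(v, tr$latency_ms[i])
    correct_mean[as.character(b)] <- sum(v) / length(v)
  }
  pooled_sd <- function(bs) {
    v <- c()
    for (i in seq_len(nrow(tr)))
      if (tr$block[i] %in% bs) v <- c(v, tr$latency_ms[i])
    m <- sum(v) / length(v)
    sqrt(sum((v - m)^2) / (length(v) - 1))
  }
  s36 <- pooled_sd(c(3, 6)); s47 <- pooled_sd(c(4, 7))
  adjusted_mean <- c()
  for (b in blocks) {
    v <- c()
    for (i in seq_len(nrow(tr)))
      if (tr$block[i] == b) {
        v <- c(v, if (tr$error[i] == 1)
          correct_mean[as.character(b)] + 600 else tr$latency_ms[i])
      }
    adjusted_mean[as.character(b)] <- sum(v) / length(v)
  }
  pairing_of <- function(b) tr$pairing[tr$block == b][1]
  signed <- function(b_a, b_b) {
    # poor_good minus rich_good within the pair
    if (pairing_of(b_b) == "poor_good")
      adjusted_mean[as.character(b_b)] - adjusted_mean[as.character(b_a)]
    else
      adjusted_mean[as.character(b_a)] - adjusted_mean[as.character(b_b)]
  }
  unname((signed(3, 6) / s36 + signed(4, 7) / s47) / 2)
}

# compact trial-table factory: latencies/errors per scored block, with
# pairing roles (blocks 3/4 rich_good, 6/7 poor_good unless swapped)
make_trials <- function(b3, b4, b6, b7,
                        e3 = 0 * b3, e4 = 0 * b4, e6 = 0 * b6, e7 = 0 * b7,
                        swap_pairing = FALSE) {
  pair_a <- if (swap_pairing) "poor_good" else "rich_good"
  pair_b <- if (swap_pairing) "rich_good" else "poor_good"
  blk <- function(b, lat, err, pairing)
    data.frame(block = b, trial_index = seq_along(lat), latency_ms = lat,
               error = as.integer(err), pairing = pairing,
               stringsAsFactors = FALSE)
  rbind(blk(3, b3, e3, pair_a), blk(4, b4, e4, pair_a),
        blk(6, b6, e6, pair_b), blk(7, b7, e7, pair_b))
}

# random small-but-valid trial set for property tests
random_trials <- function() {
  sizes <- c(`3` = sample(5:12, 1), `4` = sample(8:20, 1),
             `6` = sample(5:12, 1), `7` = sample(8:20, 1))
  lat <- lapply(sizes, function(n) {
    v <- round(rlnorm(n, log(800), 0.5))
    # occasionally push a trial over the cap
    if (runif(1) < 0.3) v[1] <- round(runif(1, 10001, 15000))
    v
  })
  err <- lapply(sizes, function(n) {
    e <- rbinom(n, 1, 0.2)
    e[1:2] <- 0L  # keep at least two correct trials per block
    e
  })
  make_trials(lat[["3"]], lat[["4"]], lat[["6"]], lat[["7"]],
              err[["3"]], err[["4"]], err[["6"]], err[["7"]],
              swap_pairing = runif(1) < 0.5)
}

# exclusion-cascade fixture: one participant's 7 blocks with exact counts of
# fast (<300 ms), slow (>10 000 ms) and error trials placed in chosen blocks
participant_fixture <- function(id, fast = c(), slow = c(), errors = c(),
                                timestamp = "2019-06-01T08:00:00Z") {
  rows <- lapply(1:7, function(b) {
    n <- c(20, 20, 20, 40, 20, 20, 40)[b]
    lat <- rep(600L, n)
    err <- rep(0L, n)
    key <- as.character(b)
    nf <- if (key %in% names(fast)) fast[[key]] else 0
    ns <- if (key %in% names(slow)) slow[[key]] else 0
    ne <- if (key %in% names(errors)) errors[[key]] else 0
    stopifnot(nf + ns <= n, ne <= n)
    if (nf > 0) lat[seq_len(nf)] <- 200L
    if (ns > 0) lat[nf + seq_len(ns)] <- 12000L
    if (ne > 0) err[seq_len(ne)] <- 1L
    pairing <- if (b %in% c(1, 2, 5)) "single_task"
               else if (b %in% c(3, 4)) "rich_good" else "poor_good"
    data.frame(participant_id = id, block = b, trial_index = seq_len(n),
               latency_ms = lat, error = err, pairing = pairing,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

demo_row <- function(id, gender = "f", income = 3L, education = 4L,
                     timestamp = "2019-06-01T08:00:00Z") {
  data.frame(participant_id = id, gender = gender,
             income_level = income, education_level = education,
             timestamp = timestamp, stringsAsFactors = FALSE)
}

# the ten printed pilot simple effects and their contrast definitions
pilot_simple_effects_table <- function() {
  data.frame(
    name = c("income_slope_men", "income_slope_women",
             "gender_diff_high_income", "gender_diff_mean_income",
             "gender_diff_low_income", "gender_by_education_low_income",
             "education_slope_women_low", "education_slope_men_low",
             "education_slope_women_high", "education_slope_men_high"),
    effect = c("income_slope", "income_slope", "gender_difference",
               "gender_difference", "gender_difference",
               "gender_by_education", "education_slope", "education_slope",
               "education_slope", "education_slope"),
    gender = c("m", "f", NA, NA, NA, NA, "f", "m", "f", "m"),
    income_z = c(0, 0, 1.5, 0, -1.5, -1.5, -1.5, -1.5, 1.5, 1.5),
    printed = c(0.106, -0.026, 0.282, 0.084, -0.114, 0.180,
                0.075, 0.255, 0.102, 0.013),
    stringsAsFactors = FALSE)
}

# per-criterion fixture pairs: counts that trip each criterion exactly at
# its printed threshold, and a boundary one trial below that must not
exclusion_criterion_fixtures <- function() {
  list(
    c1 = list(trip = list(fast = c(`3` = 7)),                 # 7/20 = 35%
              stay = list(fast = c(`3` = 6))),                # 30%
    c2 = list(trip = list(fast = c(`4` = 10)),                # 10/40 = 25%
              stay = list(fast = c(`4` = 9))),
    c3 = list(trip = list(fast = c(`4` = 4, `7` = 4)),        # 8/80 = 10%
              stay = list(fast = c(`4` = 4, `7` = 3))),
    c4 = list(trip = list(errors = c(`3` = 10)),              # 10/20 = 50%
              stay = list(errors = c(`3` = 9))),
    c5 = list(trip = list(errors = c(`3` = 8, `6` = 8)),      # 16/40 = 40%
              stay = list(errors = c(`3` = 8, `6` = 7))),
    c6 = list(trip = list(errors = c(`4` = 16)),              # 16/40 = 40%
              stay = list(errors = c(`4` = 15))),
    c7 = list(trip = list(errors = c(`4` = 12, `7` = 12)),    # 24/80 = 30%
              stay = list(errors = c(`4` = 12, `7` = 11))),   # 28.75%
    c8 = list(trip = list(slow = c(`4` = 4, `7` = 4)),        # 8/80 = 10%
              stay = list(slow = c(`4` = 4, `7` = 0)))        # 4/80 = 5%
  )
}
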