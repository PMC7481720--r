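# Improved-algorithm IAT D scoring.
#
# The score is built from blocks 3, 4, 6, 7 only, in nine ordered steps:
# (1) take all trials of those blocks; (2) drop trials with latency strictly
# exceeding 10 000 ms; (3) per-block mean of correct latencies; (4) one
# pooled sample SD (n - 1) over all retained trials -- correct and error --
# of blocks {3, 6} and another over {4, 7}, computed before any error
# replacement; (5) replace each error latency with its block's correct mean
# plus 600 ms; (6) per-block adjusted means; (7) mean differences between
# the two pairings within the practice pair and within the critical pair;
# (8) divide each difference by its pooled SD; (9) average the two
# quotients. Positive D means faster responding when rich shares a key with
# good, established from the recorded pairing roles rather than block
# presentation order.

#' Score one participant's IAT trials
#'
#' @param trials Data.frame with columns `block` (must include 3, 4, 6, 7),
#'   `latency_ms`, `error` (0/1), and `pairing` (`rich_good` / `poor_good`
#'   for the scored blocks).
#' @param latency_cap_ms Trials with latency strictly above this are dropped
#'   (default 10 000 ms).
#' @param error_penalty_ms Penalty added to the block's correct mean when
#'   replacing an error latency (default 600 ms).
#' @return An object of class `iat_dscore`: list with elements `d`,
#'   `quotient_practice` (blocks 6-3 pair), `quotient_critical` (7-4 pair),
#'   `pooled_sd_36`, `pooled_sd_47`, `n_trials_over_10s_removed`, and
#'   `block_summary` (per-block trial counts, correct means and adjusted
#'   means).
#' @examples
#' tr <- generate_iat_trials("P1", latency_model(), 0.5, seed = 7)
#' score_iat(tr)$d
#' @export
score_iat <- function(trials, latency_cap_ms = LATENCY_CAP_MS,
                      error_penalty_ms = ERROR_PENALTY_MS) {
  needed <- c("block", "latency_ms", "error", "pairing")
  if (!all(needed %in% names(trials)))
    iat_stop(paste("`trials` must have columns:", paste(needed, collapse = ", ")),
             "iatpower_validation_error")
  tr <- trials[trials$block %in% IAT_SCORED_BLOCKS, needed]
  missing_blocks <- setdiff(IAT_SCORED_BLOCKS, unique(tr$block))
  if (length(missing_blocks))
    iat_stop(paste("missing scored block(s):",
                   paste(missing_blocks, collapse = ", ")),
             "iatpower_empty_block_error")

  # step 2: strict cap -- exactly 10 000 ms is retained
  over <- tr$latency_ms > latency_cap_ms
  n_removed <- sum(over)
  tr <- tr[!over, , drop = FALSE]

  for (b in IAT_SCORED_BLOCKS) {
    bt <- tr[tr$block == b, ]
    if (nrow(bt) < 2L)
      iat_stop(sprintf("block %d has fewer than 2 trials after the 10 000 ms removal", b),
               "iatpower_empty_block_error")
    if (!any(bt$error == 0L))
      iat_stop(sprintf("block %d has no correct trials", b),
               "iatpower_empty_block_error")
  }

  # step 3: correct-trial means per block
  correct_mean <- vapply(IAT_SCORED_BLOCKS, function(b) {
    mean(tr$latency_ms[tr$block == b & tr$error == 0L])
  }, numeric(1))
  names(correct_mean) <- IAT_SCORED_BLOCKS

  # step 4: pooled sample SDs on raw retained latencies (before replacement)
  pooled_sd_36 <- sd(tr$latency_ms[tr$block %in% c(3L, 6L)])
  pooled_sd_47 <- sd(tr$latency_ms[tr$block %in% c(4L, 7L)])
  if (!is.finite(pooled_sd_36) || pooled_sd_36 <= 0 ||
      !is.finite(pooled_sd_47) || pooled_sd_47 <= 0)
    iat_stop("pooled latency SD is zero or undefined (degenerate input)",
             "iatpower_degenerate_error")

  # steps 5-6: error replacement, adjusted block means
  adj <- tr$latency_ms
  err <- tr$error == 1L
  adj[err] <- correct_mean[as.character(tr$block[err])] + error_penalty_ms
  adjusted_mean <- vapply(IAT_SCORED_BLOCKS, function(b) {
    mean(adj[tr$block == b])
  }, numeric(1))
  names(adjusted_mean) <- IAT_SCORED_BLOCKS

  # step 7: pairing-role-based differences (incompatible minus compatible)
  pairing_of <- vapply(IAT_SCORED_BLOCKS, function(b) {
    p <- unique(tr$pairing[tr$block == b])
    if (length(p) != 1L || !p %in% c("rich_good", "poor_good"))
      iat_stop(sprintf("block %d must have a single pairing role of rich_good or poor_good", b),
               "iatpower_validation_error")
    p
  }, character(1))
  names(pairing_of) <- IAT_SCORED_BLOCKS
  signed_diff <- function(pair) {
    pg <- pair[pairing_of[as.character(pair)] == "poor_good"]
    rg <- pair[pairing_of[as.character(pair)] == "rich_good"]
    if (length(pg) != 1L || length(rg) != 1L)
      iat_stop("each block pair needs one rich_good and one poor_good block",
               "iatpower_validation_error")
    adjusted_mean[as.character(pg)] - adjusted_mean[as.character(rg)]
  }

  # steps 8-9
  quotient_practice <- unname(signed_diff(c(3L, 6L)) / pooled_sd_36)
  quotient_critical <- unname(signed_diff(c(4L, 7L)) / pooled_sd_47)
  d <- (quotient_practice + quotient_critical) / 2

  structure(list(
    d = d,
    quotient_practice = quotient_practice,
    quotient_critical = quotient_critical,
    pooled_sd_36 = pooled_sd_36,
    pooled_sd_47 = pooled_sd_47,
    n_trials_over_10s_removed = n_removed,
    block_summary = data.frame(
      block_id = IAT_SCORED_BLOCKS,
      pairing = unname(pairing_of),
      n_trials_used = vapply(IAT_SCORED_BLOCKS,
                             function(b) sum(tr$block == b), integer(1)),
      mean_correct_latency = unname(correct_mean),
      adjusted_mean = unname(adjusted_mean))
  ), class = "iat_dscore")
}

#' @export
print.iat_dscore <- function(x, ...) {
  cat(sprintf("IAT D score: %.4f (practice quotient %.4f, critical quotient %.4f)\n",
              x$d, x$quotient_practice, x$quotient_critical))
  cat(sprintf("pooled SDs: %.1f ms (3/6), %.1f ms (4/7); %d trial(s) > 10 s removed\n",
              x$pooled_sd_36, x$pooled_sd_47, x$n_trials_over_10s_removed))
  invisible(x)
}

#' Score every participant in a trial table
#'
#' @param trials Data.frame of trials for many participants
#'   (`participant_id` column plus the columns required by [score_iat()]).
#' @inheritParams score_iat
#' @return Data.frame with one row per participant: `participant_id`, `d`,
#'   `quotient_practice`, `quotient_critical`, `pooled_sd_36`,
#'   `pooled_sd_47`, `n_trials_over_10s_removed`.
#' @export
score_iat_all <- function(trials, latency_cap_ms = LATENCY_CAP_MS,
                          error_penalty_ms = ERROR_PENALTY_MS) {
  if (!"participant_id" %in% names(trials))
    iat_stop("`trials` must have a participant_id column",
             "iatpower_validation_error")
  ids <- unique(trials$participant_id)
  idx <- split(seq_len(nrow(trials)), trials$participant_id)
  rows <- lapply(ids, function(id) {
    s <- score_iat(trials[idx[[id]], , drop = FALSE], latency_cap_ms,
                   error_penalty_ms)
    data.frame(participant_id = id, d = s$d,
               quotient_practice = s$quotient_practice,
               quotient_critical = s$quotient_critical,
               pooled_sd_36 = s$pooled_sd_36, pooled_sd_47 = s$pooled_sd_47,
               n_trials_over_10s_removed = s$n_trials_over_10s_removed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
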