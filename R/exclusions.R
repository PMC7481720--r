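# Participant-level exclusion cascade: deduplication by earliest timestamp,
# eight latency/error criteria evaluated on the raw trials as administered
# (before the 10 000 ms trial removal used in scoring), then ordered
# demographic-completeness exclusions (income, education, gender).
#
# All eight criteria are evaluated for every participant; only the audit
# attribution (first_matching_criterion) follows the fixed order. Thresholds
# are inclusive ("greater than or equal to") and compared in exact integer
# arithmetic (100 * count >= threshold * n) to avoid floating-point boundary
# artifacts at the printed percentages.

#' Deduplicate participant records by earliest timestamp
#'
#' When the same participant ID appears more than once, only the record with
#' the earliest timestamp is kept.
#'
#' @param participants Data.frame with `participant_id` and an ISO-8601
#'   `timestamp` column.
#' @return List with `participants` (deduplicated, original order of first
#'   appearance), `n_duplicates_dropped`, and `duplicate_ids`.
#' @examples
#' d <- data.frame(participant_id = c("a", "a"),
#'                 timestamp = c("2019-01-02T00:00:00Z", "2019-01-01T00:00:00Z"))
#' deduplicate_participants(d)$participants$timestamp
#' @export
deduplicate_participants <- function(participants) {
  ts <- as.POSIXct(participants$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                   tz = "UTC")
  bad <- which(is.na(ts) & !is.na(participants$timestamp) |
                 is.na(participants$timestamp))
  if (length(bad))
    iat_stop(sprintf("unparseable timestamp in row(s): %s",
                     paste(head(bad, 5), collapse = ", ")),
             "iatpower_validation_error")
  ord <- order(ts)
  first <- !duplicated(participants$participant_id[ord])
  keep_rows <- sort(ord[first])
  dup_ids <- unique(participants$participant_id[duplicated(participants$participant_id)])
  list(participants = participants[keep_rows, , drop = FALSE],
       n_duplicates_dropped = nrow(participants) - length(keep_rows),
       duplicate_ids = dup_ids)
}

# per-participant counts needed by the eight criteria
criterion_counts <- function(trials, practice_blocks, critical_blocks,
                             fast_cutoff_ms = FAST_CUTOFF_MS,
                             slow_cutoff_ms = LATENCY_CAP_MS) {
  per_block <- function(blocks, fun) {
    vapply(blocks, function(b) {
      bt <- trials[trials$block == b, , drop = FALSE]
      if (nrow(bt) == 0L)
        iat_stop(sprintf("block %d has no trials", b), "iatpower_empty_block_error")
      fun(bt)
    }, numeric(2))
  }
  fast <- function(bt) c(sum(bt$latency_ms < fast_cutoff_ms), nrow(bt))
  errs <- function(bt) c(sum(bt$error == 1L), nrow(bt))
  slow <- function(bt) c(sum(bt$latency_ms > slow_cutoff_ms), nrow(bt))
  list(fast_practice = per_block(practice_blocks, fast),
       fast_critical = per_block(critical_blocks, fast),
       err_practice = per_block(practice_blocks, errs),
       err_critical = per_block(critical_blocks, errs),
       slow_critical = per_block(critical_blocks, slow))
}

# inclusive percentage threshold on exact integers
meets <- function(count, n, pct) 100 * count >= pct * n

#' Evaluate the eight IAT careless-responding criteria
#'
#' Criteria (inclusive thresholds): (1) >= 35% responses under 300 ms in any
#' one practice block; (2) >= 25% under 300 ms in any one critical block;
#' (3) >= 10% under 300 ms in critical blocks pooled; (4) >= 50% error rate
#' in any one practice block; (5) >= 40% error rate in practice blocks
#' pooled; (6) >= 40% error rate in any one critical block; (7) >= 30% error
#' rate in critical blocks pooled; (8) >= 10% responses over 10 000 ms in
#' critical blocks pooled.
#'
#' "Practice blocks" are the dual-categorization practice blocks (3 and 6 by
#' default) and "critical blocks" are 4 and 7; the single-task blocks 1, 2
#' and 5 do not enter any criterion by default, but the mapping is
#' configurable.
#'
#' @param trials Trial table for one or more participants (`participant_id`,
#'   `block`, `latency_ms`, `error`).
#' @param practice_blocks,critical_blocks Block id vectors.
#' @param fast_cutoff_ms,slow_cutoff_ms Latency cutoffs for the "fast"
#'   (300 ms) and "over-long" (10 000 ms) criteria.
#' @param thresholds Named percentage thresholds `c1`..`c8`.
#' @return Data.frame with one row per participant: logical columns
#'   `c1`..`c8`, the underlying proportions, `excluded_iat` and
#'   `first_criterion` (`"c1"`..`"c8"` or `NA`).
#' @export
apply_iat_criteria <- function(trials,
                               practice_blocks = IAT_PRACTICE_BLOCKS,
                               critical_blocks = IAT_CRITICAL_BLOCKS,
                               fast_cutoff_ms = FAST_CUTOFF_MS,
                               slow_cutoff_ms = LATENCY_CAP_MS,
                               thresholds = EXCLUSION_THRESHOLDS) {
  ids <- unique(trials$participant_id)
  idx <- split(seq_len(nrow(trials)), trials$participant_id)
  th <- thresholds
  rows <- lapply(ids, function(id) {
    tr <- trials[idx[[id]], , drop = FALSE]
    cc <- criterion_counts(tr, practice_blocks, critical_blocks,
                           fast_cutoff_ms, slow_cutoff_ms)
    pool <- function(m) c(sum(m[1, ]), sum(m[2, ]))
    fp <- cc$fast_practice; fc <- cc$fast_critical
    ep <- cc$err_practice; ec <- cc$err_critical; sc <- cc$slow_critical
    fcp <- pool(fc); epp <- pool(ep); ecp <- pool(ec); scp <- pool(sc)
    crit <- c(
      c1 = any(meets(fp[1, ], fp[2, ], th[["c1"]])),
      c2 = any(meets(fc[1, ], fc[2, ], th[["c2"]])),
      c3 = meets(fcp[1], fcp[2], th[["c3"]]),
      c4 = any(meets(ep[1, ], ep[2, ], th[["c4"]])),
      c5 = meets(epp[1], epp[2], th[["c5"]]),
      c6 = any(meets(ec[1, ], ec[2, ], th[["c6"]])),
      c7 = meets(ecp[1], ecp[2], th[["c7"]]),
      c8 = meets(scp[1], scp[2], th[["c8"]])
    )
    data.frame(participant_id = id,
               c1 = crit[["c1"]], c2 = crit[["c2"]], c3 = crit[["c3"]],
               c4 = crit[["c4"]], c5 = crit[["c5"]], c6 = crit[["c6"]],
               c7 = crit[["c7"]], c8 = crit[["c8"]],
               max_fast_prop_practice = max(fp[1, ] / fp[2, ]),
               max_fast_prop_critical = max(fc[1, ] / fc[2, ]),
               pooled_fast_prop_critical = fcp[1] / fcp[2],
               max_error_rate_practice = max(ep[1, ] / ep[2, ]),
               pooled_error_rate_practice = epp[1] / epp[2],
               max_error_rate_critical = max(ec[1, ] / ec[2, ]),
               pooled_error_rate_critical = ecp[1] / ecp[2],
               pooled_slow_prop_critical = scp[1] / scp[2],
               excluded_iat = any(crit),
               first_criterion = if (any(crit)) names(crit)[which(crit)[1]]
                                 else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordered demographic-completeness exclusions
#'
#' Missing income (including the "I don't know" option, which arrives here
#' as `NA`), then missing education, then missing gender, attributed in that
#' order: a participant missing both income and education counts under
#' income.
#'
#' @param participants Demographics data.frame (`participant_id`, `gender`,
#'   `income_level`, `education_level`).
#' @return Data.frame with logical flags and `demographic_exclusion`
#'   (`"missing_income"`, `"missing_education"`, `"missing_gender"` or `NA`).
#' @export
apply_demographic_exclusions <- function(participants) {
  mi <- is.na(participants$income_level)
  me <- is.na(participants$education_level)
  mg <- is.na(participants$gender) | !nzchar(as.character(participants$gender))
  first <- ifelse(mi, "missing_income",
                  ifelse(me, "missing_education",
                         ifelse(mg, "missing_gender", NA_character_)))
  data.frame(participant_id = participants$participant_id,
             missing_income = mi, missing_education = me, missing_gender = mg,
             demographic_exclusion = first, stringsAsFactors = FALSE)
}

#' Run the full exclusion cascade
#'
#' Deduplication, the eight IAT criteria, then ordered demographic
#' exclusions, with one audit row per unique participant. The
#' `first_matching_criterion` attribution order is: `duplicate_id` (for the
#' dropped later records), `c1`..`c8`, `missing_income`,
#' `missing_education`, `missing_gender`, `none`.
#'
#' @param trials Trial table (all participants).
#' @param demographics Demographics table (may contain duplicate IDs).
#' @inheritParams apply_iat_criteria
#' @return List with `report` (one row per retained-or-excluded unique
#'   participant plus per-criterion statistics and `all_matching_criteria`),
#'   `retained_ids`, `n_duplicates_dropped` and `summary` (counts in the
#'   analysis accounting order).
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 12, seed = 5,
#'                                      missing_income_rate = 0.2))
#' exclusion_cascade(coh$trials, coh$demographics)$summary
#' @export
exclusion_cascade <- function(trials, demographics,
                              practice_blocks = IAT_PRACTICE_BLOCKS,
                              critical_blocks = IAT_CRITICAL_BLOCKS) {
  dedup <- deduplicate_participants(demographics)
  demo <- dedup$participants
  iat <- apply_iat_criteria(trials, practice_blocks, critical_blocks)
  dem <- apply_demographic_exclusions(demo)

  report <- merge(iat, dem, by = "participant_id", all = TRUE, sort = FALSE)
  report <- report[match(demo$participant_id, report$participant_id), ]
  crit_cols <- paste0("c", 1:8)
  crit_mat <- as.matrix(report[crit_cols])
  all_crit <- vapply(seq_len(nrow(report)), function(i) {
    hit <- crit_cols[crit_mat[i, ] %in% TRUE]
    dm <- report$demographic_exclusion[i]
    paste(c(hit, if (!is.na(dm)) dm), collapse = ",")
  }, character(1))
  first <- ifelse(report$excluded_iat %in% TRUE, report$first_criterion,
                  report$demographic_exclusion)
  first[is.na(first)] <- "none"
  report$all_matching_criteria <- all_crit
  report$first_matching_criterion <- first
  report$excluded <- first != "none"
  rownames(report) <- NULL

  retained <- report$participant_id[!report$excluded]
  summary <- c(n_input = nrow(demographics),
               n_duplicates_dropped = dedup$n_duplicates_dropped,
               n_iat_excluded = sum(report$excluded_iat %in% TRUE),
               n_missing_income = sum(first == "missing_income"),
               n_missing_education = sum(first == "missing_education"),
               n_missing_gender = sum(first == "missing_gender"),
               n_retained = length(retained))
  list(report = report, retained_ids = retained,
       n_duplicates_dropped = dedup$n_duplicates_dropped,
       duplicate_ids = dedup$duplicate_ids,
       summary = summary)
}

#' Print an exclusion ledger in the analysis accounting order
#'
#' @param cascade Result of [exclusion_cascade()].
#' @return The summary vector, invisibly.
#' @export
exclusion_summary <- function(cascade) {
  s <- cascade$summary
  cat(sprintf("participants in:            %d\n", s[["n_input"]]))
  cat(sprintf("duplicate records dropped:  %d\n", s[["n_duplicates_dropped"]]))
  cat(sprintf("IAT criteria (c1-c8):       %d\n", s[["n_iat_excluded"]]))
  cat(sprintf("missing income:             %d\n", s[["n_missing_income"]]))
  cat(sprintf("missing education:          %d\n", s[["n_missing_education"]]))
  cat(sprintf("missing gender:             %d\n", s[["n_missing_gender"]]))
  cat(sprintf("retained for analysis:      %d\n", s[["n_retained"]]))
  invisible(s)
}
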