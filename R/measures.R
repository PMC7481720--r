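# Explicit rich-versus-poor measures: fourteen difference/average scores,
# the weighted attitudinal ambivalence index, and the descriptive machinery
# (one-sample t-tests, Pearson correlations with the IAT D score).

#' Attitudinal ambivalence index
#'
#' `min(positive, negative) / (6 + max(positive, negative) -
#' min(positive, negative))` for 1-6 monopolar positivity and negativity
#' ratings of the same target. Symmetric in its arguments and bounded in
#' `[1/11, 1]`; larger when positive and negative evaluations are both
#' intense, giving more weight to equally *high* than to equally low pairs.
#'
#' @param positive,negative Integer ratings in 1..6 (vectorized).
#' @return Ambivalence scores.
#' @examples
#' ambivalence(6, 6)   # 1
#' ambivalence(1, 1)   # 1/6
#' ambivalence(6, 1)   # 1/11
#' @export
ambivalence <- function(positive, negative) {
  for (nm in c("positive", "negative")) {
    x <- get(nm)
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 1 | x > 6) ||
        any(x != round(x)))
      iat_stop(sprintf("`%s` ratings must be integers in 1..6", nm),
               "iatpower_validation_error")
  }
  pmin(positive, negative) / (6 + pmax(positive, negative) -
                                pmin(positive, negative))
}

measure_label <- function(code) {
  labs <- vapply(EXPLICIT_MEASURES, `[[`, character(1), "label")
  codes <- vapply(EXPLICIT_MEASURES, `[[`, integer(1), "code")
  labs[match(code, codes)]
}

# mean response per target for one participant's items of one measure
target_mean <- function(items, tgt) {
  v <- items$response[items$target == tgt]
  if (!length(v)) NA_real_ else mean(v)
}

score_one_measure <- function(code, items) {
  n_used <- nrow(items)
  val <- switch(as.character(code),
    # bipolar, reverse-coded: positive raw = prefers poor, flip to pro-rich
    "2" = -mean(items$response[items$target == "both"]),
    "9" = -mean(items$response[items$target == "both"]),
    # polarity: average of the two items, no differencing
    "12" = mean(items$response[items$target == "both"]),
    {
      r <- target_mean(items, "rich")
      p <- target_mean(items, "poor")
      if (is.na(r) || is.na(p)) NA_real_ else r - p
    })
  list(value = val, n_items_used = n_used)
}

#' Build participant-level explicit measure scores
#'
#' Rich-minus-poor differences for the separately-rated measures, with
#' multi-item components averaged within target before differencing;
#' reverse-coding of the bipolar others'-evaluations (2) and relative
#' personal preference (9) items so positive always means pro-rich;
#' polarity (12) as the plain average of its two items. The ambivalence
#' score (reported under measure code 7) is
#' `ambivalence(rich) - ambivalence(poor)` computed from the monopolar
#' positive (code 7) and negative (code 8) items. Measures 15-18 are
#' tolerated in the input but never scored. Participants missing all items
#' needed for a measure get no row for it.
#'
#' @param items Item table (`participant_id`, `measure_code`, `item_code`,
#'   `target`, `response`).
#' @return Data.frame `participant_id`, `measure_code`, `label`, `value`,
#'   `n_items_used`.
#' @examples
#' it <- generate_explicit_items("P1", seed = 11)
#' build_measures(it)
#' @export
build_measures <- function(items) {
  bad <- setdiff(unique(items$measure_code), 1:18)
  if (length(bad))
    iat_stop(paste("unknown measure code(s):", paste(bad, collapse = ", ")),
             "iatpower_validation_error")
  items <- items[items$measure_code %in% 1:14, , drop = FALSE]
  rows <- list()
  for (id in unique(items$participant_id)) {
    pi <- items[items$participant_id == id, , drop = FALSE]
    # ambivalence needs all four monopolar items (codes 7 and 8)
    amb <- NULL
    mono <- pi[pi$measure_code %in% c(7L, 8L), , drop = FALSE]
    if (nrow(mono)) {
      g <- function(code, tgt) {
        v <- mono$response[mono$measure_code == code & mono$target == tgt]
        if (length(v) == 1L) v else NA_real_
      }
      pr <- g(7L, "rich"); nr <- g(8L, "rich")
      pp <- g(7L, "poor"); np <- g(8L, "poor")
      if (!anyNA(c(pr, nr, pp, np)))
        amb <- list(value = ambivalence(pr, nr) - ambivalence(pp, np),
                    n_items_used = 4L)
    }
    for (code in sort(unique(pi$measure_code))) {
      if (code == 8L) next
      if (code == 7L) {
        sc <- amb
        if (is.null(sc)) next
      } else {
        sc <- score_one_measure(code, pi[pi$measure_code == code, , drop = FALSE])
        if (is.na(sc$value)) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = id, measure_code = as.integer(code),
        label = if (code == 7L) "ambivalence" else measure_label(code),
        value = sc$value, n_items_used = sc$n_items_used,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sample t-test summary
#'
#' Two-sided one-sample t-test with 95% confidence interval, as used for the
#' descriptive table of explicit measures (tested against 0 for difference
#' scores; polarity is tested against its scale midpoint 3.5).
#'
#' @param values Numeric vector (>= 2 finite values).
#' @param mu Null value.
#' @return List: `mean`, `ci_low`, `ci_high`, `t`, `df`, `p`, `n`.
#' @examples
#' one_sample_test(c(1, 2, 3, 4, 5), mu = 0)$t  # 4.2426
#' @export
one_sample_test <- function(values, mu = 0) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L)
    iat_stop("need at least 2 finite values for a one-sample t-test",
             "iatpower_validation_error")
  m <- mean(values)
  se <- sd(values) / sqrt(n)
  df <- n - 1
  if (se == 0) {
    # degenerate constant vector: t = 0 / p = 1 when the mean equals mu
    tval <- if (m == mu) 0 else sign(m - mu) * Inf
    return(list(mean = m, ci_low = m, ci_high = m, t = tval, df = df,
                p = if (m == mu) 1 else 0, n = n))
  }
  tval <- (m - mu) / se
  tcrit <- qt(0.975, df)
  list(mean = m, ci_low = m - tcrit * se, ci_high = m + tcrit * se,
       t = tval, df = df, p = 2 * pt(-abs(tval), df), n = n)
}

#' Pearson correlation with IAT D scores
#'
#' Pairwise-complete Pearson correlation with two-sided p-value; the n of
#' complete pairs is reported because item randomization makes it vary by
#' measure.
#'
#' @param values Measure values.
#' @param d D scores, aligned with `values`.
#' @return List: `r`, `n`, `p`.
#' @export
correlate_with_d <- function(values, d) {
  ok <- is.finite(values) & is.finite(d)
  if (sum(ok) < 3L)
    iat_stop("need at least 3 complete pairs for a correlation",
             "iatpower_validation_error")
  ct <- cor.test(values[ok], d[ok], method = "pearson")
  list(r = unname(ct$estimate), n = sum(ok), p = ct$p.value)
}

#' Descriptive one-sample tests for all measures
#'
#' @param measures Output of [build_measures()].
#' @return Data.frame (one row per scored measure): `measure_code`, `label`,
#'   `mu`, `mean`, `ci_low`, `ci_high`, `t`, `df`, `p`.
#' @export
measure_descriptives <- function(measures) {
  rows <- lapply(sort(unique(measures$measure_code)), function(code) {
    v <- measures$value[measures$measure_code == code]
    mu <- if (code == 12L) 3.5 else 0
    tt <- one_sample_test(v, mu = mu)
    data.frame(measure_code = code,
               label = measures$label[measures$measure_code == code][1],
               mu = mu, mean = tt$mean, ci_low = tt$ci_low,
               ci_high = tt$ci_high, t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlations of all measures with the IAT D score
#'
#' @param measures Output of [build_measures()].
#' @param scores Output of [score_iat_all()] (or any data.frame with
#'   `participant_id` and `d`).
#' @return Data.frame: `measure_code`, `label`, `r`, `n`, `p`.
#' @export
measure_iat_correlations <- function(measures, scores) {
  rows <- lapply(sort(unique(measures$measure_code)), function(code) {
    m <- measures[measures$measure_code == code, ]
    d <- scores$d[match(m$participant_id, scores$participant_id)]
    ct <- correlate_with_d(m$value, d)
    data.frame(measure_code = code, label = m$label[1],
               r = ct$r, n = ct$n, p = ct$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
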