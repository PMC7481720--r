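# Exclusion cascade: deduplication, the eight careless-responding criteria
# with trip/boundary fixture pairs, ordered demographic exclusions, and the
# bookkeeping invariants of the audit report.

test_that("deduplication keeps the earliest record per id", {
  d <- rbind(demo_row("a", timestamp = "2019-06-02T00:00:00Z"),
             demo_row("a", timestamp = "2019-06-01T00:00:00Z"),
             demo_row("b", timestamp = "2019-06-03T00:00:00Z"))
  res <- deduplicate_participants(d)
  expect_identical(res$n_duplicates_dropped, 1L)
  expect_identical(res$duplicate_ids, "a")
  expect_identical(res$participants$timestamp[res$participants$participant_id == "a"],
                   "2019-06-01T00:00:00Z")

  # no duplicates -> identity
  clean <- rbind(demo_row("a"), demo_row("b", timestamp = "2019-06-01T08:01:00Z"))
  expect_identical(deduplicate_participants(clean)$participants, clean)

  # three records, one id -> exactly one survivor
  trip <- rbind(demo_row("x", timestamp = "2019-06-03T00:00:00Z"),
                demo_row("x", timestamp = "2019-06-01T00:00:00Z"),
                demo_row("x", timestamp = "2019-06-02T00:00:00Z"))
  res3 <- deduplicate_participants(trip)
  expect_identical(nrow(res3$participants), 1L)
  expect_identical(res3$n_duplicates_dropped, 2L)

  bad <- demo_row("a", timestamp = "not-a-time")
  expect_error(deduplicate_participants(bad), class = "iatpower_validation_error")
})

criterion_fixtures <- exclusion_criterion_fixtures()

test_that("every criterion trips at its threshold and not one trial below", {
  for (crit in names(criterion_fixtures)) {
    fx <- criterion_fixtures[[crit]]
    trip <- do.call(participant_fixture, c(list(id = "t"), fx$trip))
    stay <- do.call(participant_fixture, c(list(id = "s"), fx$stay))
    rt <- apply_iat_criteria(trip)
    rs <- apply_iat_criteria(stay)
    expect_true(rt[[crit]], label = paste(crit, "trip fixture"))
    expect_identical(rt$first_criterion, crit)
    expect_false(rs[[crit]], label = paste(crit, "boundary fixture"))
    if (crit %in% c("c3", "c8"))  # the pooled boundary must not trip per-block twins
      expect_false(rs$excluded_iat)
  }
})

test_that("criteria are evaluated on raw trials, before the 10 s removal", {
  # four 12 s trials per critical block: removed in scoring, but counted here
  tr <- do.call(participant_fixture,
                list(id = "p", slow = c(`4` = 4, `7` = 4)))
  rep <- apply_iat_criteria(tr)
  expect_true(rep$c8)
  expect_equal(rep$pooled_slow_prop_critical, 0.1)
})

test_that("demographic exclusions are attributed in income > education > gender order", {
  d <- rbind(demo_row("a", income = NA, education = NA),
             demo_row("b", income = NA),
             demo_row("c", education = NA),
             demo_row("d", gender = NA),
             demo_row("e"))
  res <- apply_demographic_exclusions(d)
  expect_identical(res$demographic_exclusion,
                   c("missing_income", "missing_income", "missing_education",
                     "missing_gender", NA))
})

test_that("the cascade is idempotent, conserving, and reports all matches", {
  set.seed(7)
  trials <- rbind(
    participant_fixture("p1", fast = c(`3` = 7), errors = c(`4` = 16)),  # c1+c6
    participant_fixture("p2"),
    participant_fixture("p3", slow = c(`4` = 4, `7` = 4)))               # c8
  demo <- rbind(demo_row("p1"),
                demo_row("p2", income = NA,
                         timestamp = "2019-06-01T08:01:00Z"),
                demo_row("p3", timestamp = "2019-06-01T08:02:00Z"),
                demo_row("p3", timestamp = "2019-06-02T08:02:00Z"))  # duplicate
  c1 <- exclusion_cascade(trials, demo)
  c2 <- exclusion_cascade(trials, c1$report[, c("participant_id"), drop = FALSE] |>
                            merge(demo[!duplicated(demo$participant_id), ],
                                  by = "participant_id"))
  expect_identical(c1$report$first_matching_criterion,
                   c2$report$first_matching_criterion)
  expect_identical(c1$report$first_matching_criterion[c1$report$participant_id == "p1"],
                   "c1")
  expect_identical(c1$report$all_matching_criteria[c1$report$participant_id == "p1"],
                   "c1,c6")
  expect_identical(c1$report$first_matching_criterion[c1$report$participant_id == "p2"],
                   "missing_income")
  # conservation: input rows = duplicates + first-match attributions + retained
  s <- c1$summary
  expect_identical(
    unname(s[["n_input"]]),
    s[["n_duplicates_dropped"]] + s[["n_iat_excluded"]] +
      s[["n_missing_income"]] + s[["n_missing_education"]] +
      s[["n_missing_gender"]] + s[["n_retained"]])
  expect_identical(c1$retained_ids, character(0))
})

test_that("a 274-participant cohort engineered to the pilot counts retains 175", {
  # 46 trip an IAT criterion; of the 228 clean, 49 miss income (3 of whom
  # also miss education), then 4 more miss education, none miss gender
  n <- 274
  ids <- sprintf("S%03d", seq_len(n))
  careless <- ids[1:46]
  miss_income <- ids[47:95]          # 49
  miss_edu_only <- ids[96:99]        # 4
  trials <- do.call(rbind, lapply(seq_along(ids), function(i) {
    if (ids[i] %in% careless) {
      kind <- i %% 3
      if (kind == 0) participant_fixture(ids[i], fast = c(`3` = 7))
      else if (kind == 1) participant_fixture(ids[i], errors = c(`4` = 12, `7` = 12))
      else participant_fixture(ids[i], slow = c(`4` = 4, `7` = 4))
    } else participant_fixture(ids[i])
  }))
  demo <- do.call(rbind, lapply(seq_along(ids), function(i) {
    demo_row(ids[i],
             gender = c("f", "m")[1 + i %% 2],
             income = if (ids[i] %in% miss_income) NA else 1L + i %% 5,
             education = if (ids[i] %in% miss_edu_only ||
                               ids[i] %in% miss_income[1:3]) NA else 1L + i %% 5,
             timestamp = sprintf("2019-06-01T08:%02d:%02dZ", i %/% 60, i %% 60))
  }))
  res <- exclusion_cascade(trials, demo)
  s <- res$summary
  expect_identical(unname(s[["n_iat_excluded"]]), 46L)
  expect_identical(unname(s[["n_missing_income"]]), 49L)
  expect_identical(unname(s[["n_missing_education"]]), 4L)
  expect_identical(unname(s[["n_missing_gender"]]), 0L)
  expect_identical(unname(s[["n_retained"]]), 175L)
})
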