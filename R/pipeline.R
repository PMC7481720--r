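# End-to-end orchestration: generate or ingest a cohort, score the IAT,
# apply the exclusion cascade, build explicit measures and their descriptive
# tables, fit the omnibus regression with simple effects, and (optionally)
# run the power battery. Every output is delimited text or JSON, and a run
# manifest records the configuration, file digests and per-stage row counts
# so a rerun with the same seed is byte-identical.

#' Default pipeline configuration
#'
#' A flat key-value list. Every analysis constant is surfaced here with its
#' standard default: the 300 ms fast cutoff, the 10 000 ms latency cap, the
#' 600 ms error penalty, the c1-c8 percentage thresholds, the +-1.5 s.d.
#' moderator evaluation points, alpha, and the simulation sizes.
#'
#' @param seed Integer seed (mandatory).
#' @param ... Overrides of any default entry (unknown keys are an error).
#' @return Named list of class `pipeline_config`.
#' @examples
#' default_pipeline_config(seed = 1, n_participants = 40, run_power = FALSE)
#' @export
default_pipeline_config <- function(seed, ...) {
  if (missing(seed)) iat_stop("`seed` is mandatory", "iatpower_validation_error")
  cfg <- list(
    seed = as.integer(seed),
    # synthetic cohort
    simulate = TRUE,
    n_participants = 175,
    prop_women = 115 / 175,
    income_education_corr = 0.22,
    careless_rate = 0,
    missing_income_rate = 0,
    missing_education_rate = 0,
    residual_sd = NA,            # NA -> calibrated
    incompatible_shift = 0.15,
    # scoring / exclusions
    latency_cap_ms = 10000,
    error_penalty_ms = 600,
    fast_cutoff_ms = 300,
    practice_blocks = c(3, 6),
    critical_blocks = c(4, 7),
    thresholds = EXCLUSION_THRESHOLDS,
    # regression
    outcome = "d",               # "d" or an explicit measure code 1-14
    vif_threshold = 10,
    eval_point_sd = 1.5,
    # power
    run_power = TRUE,
    power_n = 1000,
    power_reps = 1000,
    alpha = 0.05
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    iat_stop(paste("unknown config key(s):", paste(bad, collapse = ", ")),
             "iatpower_validation_error")
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a flat key-value file
#'
#' The file is flat YAML (`key: value` lines). `seed` is mandatory.
#'
#' @param path File path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    iat_stop(paste("config file not found:", path), "iatpower_validation_error")
  vals <- yaml::read_yaml(path)
  if (is.null(vals$seed))
    iat_stop("config file must set `seed`", "iatpower_validation_error")
  do.call(default_pipeline_config,
          c(list(seed = vals$seed), vals[setdiff(names(vals), "seed")]))
}

stage_msg <- function(stage, quiet, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or ingest) -> score -> exclude -> measures ->
#' regression -> power. Writes `trials.csv`, `demographics.csv`,
#' `explicit.csv`, `scores.csv`, `exclusions.csv`, `measures.csv`,
#' `table3.csv` (one-sample tests), `table4.csv` (correlations with D),
#' `model.csv`, `simple_effects.csv`, optionally `power_report.json`, and
#' `manifest.json` into `outdir`. Any stage failure aborts with the stage
#' name attached to the error message.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]) or a
#'   path to a flat key-value config file.
#' @param outdir Output directory.
#' @param indir Directory with `trials.csv`, `demographics.csv`,
#'   `explicit.csv` when `simulate` is `FALSE`.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the stage results and the manifest.
#' @examples
#' cfg <- default_pipeline_config(seed = 9, n_participants = 40,
#'                                run_power = FALSE)
#' res <- run_pipeline(cfg, outdir = tempfile(), quiet = TRUE)
#' res$manifest$row_counts
#' @export
run_pipeline <- function(config, outdir, indir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    iat_stop("`config` must be a pipeline_config or a config file path",
             "iatpower_validation_error")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  run_stage <- function(stage, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[stage]] <<- round(as.numeric(Sys.time() - st, units = "secs"), 3)
    res
  }

  residual_sd <- if (is.na(config$residual_sd)) NULL else config$residual_sd

  cohort <- run_stage("simulate", {
    if (isTRUE(config$simulate)) {
      cc <- cohort_config(n_participants = config$n_participants,
                          prop_women = config$prop_women,
                          income_education_corr = config$income_education_corr,
                          residual_sd = residual_sd,
                          careless_rate = config$careless_rate,
                          missing_income_rate = config$missing_income_rate,
                          missing_education_rate = config$missing_education_rate,
                          seed = config$seed)
      lm_ <- latency_model(incompatible_shift = config$incompatible_shift)
      coh <- generate_cohort(cc, lm_)
      write_cohort(coh, outdir)
      stage_msg("simulate", quiet, "generated %d participants, %d trials",
                nrow(coh$demographics), nrow(coh$trials))
      coh
    } else {
      if (is.null(indir))
        iat_stop("`indir` required when simulate = FALSE",
                 "iatpower_validation_error")
      coh <- list(
        trials = read.csv(file.path(indir, "trials.csv"),
                          stringsAsFactors = FALSE),
        demographics = read.csv(file.path(indir, "demographics.csv"),
                                stringsAsFactors = FALSE,
                                colClasses = c(timestamp = "character")),
        explicit = read.csv(file.path(indir, "explicit.csv"),
                            stringsAsFactors = FALSE))
      stage_msg("simulate", quiet, "ingested %d participants from %s",
                nrow(coh$demographics), indir)
      coh
    }
  })

  scores <- run_stage("score", {
    s <- score_iat_all(cohort$trials, config$latency_cap_ms,
                       config$error_penalty_ms)
    write.csv(s, file.path(outdir, "scores.csv"), row.names = FALSE)
    stage_msg("score", quiet, "scored %d participants", nrow(s))
    s
  })

  cascade <- run_stage("exclude", {
    cs <- exclusion_cascade(cohort$trials, cohort$demographics,
                            practice_blocks = config$practice_blocks,
                            critical_blocks = config$critical_blocks)
    write.csv(cs$report, file.path(outdir, "exclusions.csv"),
              row.names = FALSE)
    if (!quiet) exclusion_summary(cs)
    cs
  })
  retained <- cascade$retained_ids

  measures <- run_stage("measures", {
    m <- build_measures(
      cohort$explicit[cohort$explicit$participant_id %in% retained, ])
    write.csv(m, file.path(outdir, "measures.csv"), row.names = FALSE)
    t3 <- measure_descriptives(m)
    write.csv(t3, file.path(outdir, "table3.csv"), row.names = FALSE)
    t4 <- measure_iat_correlations(m, scores)
    write.csv(t4, file.path(outdir, "table4.csv"), row.names = FALSE)
    stage_msg("measures", quiet, "scored %d measures for %d participants",
              length(unique(m$measure_code)), length(unique(m$participant_id)))
    m
  })

  regression <- run_stage("regress", {
    keep <- cohort$demographics[cohort$demographics$participant_id %in% retained, ]
    dat <- merge(keep, scores, by = "participant_id")
    if (!identical(config$outcome, "d")) {
      mc <- as.integer(config$outcome)
      mm <- measures[measures$measure_code == mc, c("participant_id", "value")]
      dat <- merge(dat, mm, by = "participant_id")
      dat$outcome_raw <- dat$value
    } else {
      dat$outcome_raw <- dat$d
    }
    dat$d_z <- standardize(dat$outcome_raw)
    dat$income_z <- standardize(dat$income_level)
    dat$education_z <- standardize(dat$education_level)
    fit <- fit_omnibus(dat, vif_threshold = config$vif_threshold)
    write.csv(fit$coefficients, file.path(outdir, "model.csv"),
              row.names = FALSE)
    se <- simple_effects(fit)
    write.csv(se, file.path(outdir, "simple_effects.csv"), row.names = FALSE)
    stage_msg("regress", quiet, "omnibus fit on n = %d (df = %d)",
              fit$n, fit$df_residual)
    list(fit = fit, simple_effects = se, data = dat)
  })

  power <- NULL
  if (isTRUE(config$run_power)) {
    power <- run_stage("power", {
      pc <- power_config(n_per_dataset = config$power_n,
                         n_reps = config$power_reps, alpha = config$alpha,
                         residual_sd = residual_sd,
                         prop_women = config$prop_women,
                         income_education_corr = config$income_education_corr,
                         seed = config$seed + 1L)
      pr <- estimate_power(pc)
      jsonlite::write_json(
        list(n = pc$n_per_dataset, n_reps = pc$n_reps, alpha = pc$alpha,
             seed = pc$seed,
             results = pr[, c("test", "power", "mc_se", "n_significant")]),
        file.path(outdir, "power_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stage_msg("power", quiet, "power battery: %d tests x %d reps",
                nrow(pr), pc$n_reps)
      pr
    })
  }

  data_files <- list.files(outdir, pattern = "\\.(csv|json)$",
                           full.names = TRUE)
  data_files <- data_files[basename(data_files) != "manifest.json"]
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    file_digests = setNames(as.list(tools::md5sum(sort(data_files))),
                            basename(sort(data_files))),
    row_counts = list(
      participants_in = nrow(cohort$demographics),
      duplicates_dropped = cascade$n_duplicates_dropped,
      excluded_iat = unname(cascade$summary[["n_iat_excluded"]]),
      excluded_missing_income = unname(cascade$summary[["n_missing_income"]]),
      excluded_missing_education = unname(cascade$summary[["n_missing_education"]]),
      excluded_missing_gender = unname(cascade$summary[["n_missing_gender"]]),
      retained = length(retained),
      trials = nrow(cohort$trials),
      measures = nrow(measures)),
    stage_seconds = timings,
    total_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, scores = scores, cascade = cascade,
                 measures = measures, regression = regression, power = power,
                 manifest = manifest, outdir = outdir))
}
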