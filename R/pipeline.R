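#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate a cohort (or read the four input
#' tables), compute the speech-exposure table, judge trial validity and
#' aggregate condition scores, run the statistical analysis, and optionally
#' write all stage outputs plus a markdown report. Fully deterministic under
#' a fixed configuration: both the simulator and the bootstrap are seeded.
#'
#' @param config A [simulation_config()] (used when `inputs` is `NULL`).
#' @param inputs Optional named list of real input tables (`infants`,
#'   `diary`, `segments`, `trials`) or a directory containing
#'   `infants.csv`, `diary.csv`, `lena_segments.csv`, `trials.csv`.
#' @param out_dir Optional output directory; when given, writes
#'   `exposure.csv`, `scores.csv`, `results.json`, `report.md` (and, for
#'   simulated cohorts, the four input tables and `ground_truth.json`).
#' @param min_valid Minimum valid trials per condition (inclusion rule).
#' @param pooling Condition-pooling mode for the inclusion rule
#'   (see [condition_scores()]).
#' @param covariates Covariate columns for the adjusted analysis.
#' @param n_boot Bootstrap resamples for confidence intervals.
#' @param ci Compute bootstrap confidence intervals?
#' @param verbose Log per-stage row counts and exclusions to stderr.
#' @return Invisibly, a list with `cohort`, `exposure`, `scores`, `results`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_infants_per_site = c(a = 15, b = 15), seed = 7)
#' out <- run_pipeline(cfg, ci = FALSE)
#' out$results$exposure_total_face_pref$estimate
#' }
#' @export
run_pipeline <- function(config = simulation_config(), inputs = NULL,
                         out_dir = NULL, min_valid = 3,
                         pooling = c("split4", "pooled2"),
                         covariates = c(
                           "gestational_age_weeks", "maternal_education",
                           "delivery", "sex", "birth_weight_g"
                         ),
                         n_boot = 2000, ci = TRUE, verbose = FALSE) {
  pooling <- match.arg(pooling)
  log_msg <- function(...) if (verbose) message("[facepref] ", ...)

  if (is.null(inputs)) {
    cohort <- simulate_cohort(config)
    seed <- config$seed
    log_msg("simulated cohort: ", nrow(cohort$infants), " infants")
  } else {
    if (is.character(inputs)) {
      inputs <- read_cohort(inputs)
    }
    cohort <- inputs
    seed <- if (inherits(config, "simulation_config")) config$seed else 1L
    log_msg("loaded cohort: ", nrow(cohort$infants), " infants")
  }

  exposure <- exposure_table(cohort$diary, cohort$segments, cohort$infants)
  log_msg(
    "exposure rows: ", nrow(exposure), "; imputed frequencies: ",
    sum(exposure$frequency_source %in%
      c("site_median", "twin_cosample", "single_parent_zero"))
  )

  trials <- cohort$trials
  if (is.null(trials) && !is.null(cohort$gaze_streams)) {
    trials <- code_streams(cohort$gaze_streams, cohort$schedule)
  }
  trials <- trial_validity(trials)
  scores <- condition_scores(trials, min_valid = min_valid, pooling = pooling)
  log_msg(
    "scored ", nrow(scores), " infants; excluded by valid-trial rule: ",
    sum(!scores$included)
  )

  results <- analyze_cohort(
    exposure, scores, cohort$infants,
    covariates = covariates, n_boot = n_boot, ci = ci, seed = seed
  )

  if (!is.null(out_dir)) {
    write_pipeline_outputs(out_dir, cohort, exposure, scores, results,
      simulated = is.null(inputs)
    )
    log_msg("outputs written to ", out_dir)
  }
  invisible(list(
    cohort = cohort, exposure = exposure, scores = scores, results = results
  ))
}

# code every stored gaze stream against a trial schedule table
code_streams <- function(streams, schedule) {
  key <- split(
    seq_len(nrow(streams)),
    paste(streams$infant_id, streams$trial_index)
  )
  recs <- lapply(key, function(rows) {
    tr <- schedule[
      schedule$infant_id == streams$infant_id[rows[1]] &
        schedule$trial_index == streams$trial_index[rows[1]], ,
      drop = FALSE
    ]
    code_trial(streams[rows, , drop = FALSE], tr[1, ])
  })
  dplyr::bind_rows(recs)
}

#' Read a cohort from delimited input files
#'
#' Expects `infants.csv`, `diary.csv`, `lena_segments.csv`, and `trials.csv`
#' in `dir`; timestamps must be ISO-8601 and are read as UTC.
#'
#' @param dir Directory path.
#' @return A list with `infants`, `diary`, `segments`, `trials`.
#' @export
read_cohort <- function(dir) {
  rd <- function(name) {
    readr::read_csv(file.path(dir, name),
      show_col_types = FALSE, progress = FALSE,
      locale = readr::locale(tz = "UTC")
    )
  }
  list(
    infants = rd("infants.csv"),
    diary = rd("diary.csv"),
    segments = rd("lena_segments.csv"),
    trials = rd("trials.csv")
  )
}

#' Write a simulated cohort's input tables to a directory
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$infants, file.path(dir, "infants.csv"), progress = FALSE)
  readr::write_csv(cohort$diary, file.path(dir, "diary.csv"), progress = FALSE)
  readr::write_csv(cohort$segments, file.path(dir, "lena_segments.csv"), progress = FALSE)
  readr::write_csv(cohort$trials, file.path(dir, "trials.csv"), progress = FALSE)
  gt <- cohort$ground_truth
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns"
  )
  invisible(dir)
}

write_pipeline_outputs <- function(out_dir, cohort, exposure, scores, results,
                                   simulated = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (simulated) {
    write_cohort(cohort, out_dir)
  }
  readr::write_csv(exposure, file.path(out_dir, "exposure.csv"), progress = FALSE)
  readr::write_csv(scores, file.path(out_dir, "scores.csv"), progress = FALSE)
  jsonlite::write_json(
    results_to_list(results), file.path(out_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns"
  )
  writeLines(report_markdown(results), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

# strip non-serializable pieces for JSON output
results_to_list <- function(results) {
  out <- unclass(results)
  out$data <- NULL
  if (!is.null(results$twin_sensitivity)) {
    out$twin_sensitivity <- list(
      n_subsets = results$twin_sensitivity$n_subsets,
      min = results$twin_sensitivity$min,
      max = results$twin_sensitivity$max,
      median = results$twin_sensitivity$median,
      values = results$twin_sensitivity$values
    )
  }
  out <- lapply(out, function(x) if (inherits(x, "analysis_result")) unclass(x) else x)
  out
}
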