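#' Code one gaze stream into a trial record
#'
#' Classifies each gaze sample against the stimulus geometry (central
#' stimulus 9.6 x 10.2 degrees at screen centre; distractor 12 degrees
#' laterally on the cued side) and extracts: the proportion of the
#' pre-distractor period spent fixating the central stimulus, the latency and
#' direction of the first departure from the central area after distractor
#' onset, and whether a disengagement was registered within the 150--1000 ms
#' analysis window. A shift beginning at or before 150 ms is recorded
#' (premature) but not registered as disengagement; [trial_validity()] later
#' rejects such trials. Sampling gaps longer than 1.5 sample periods inside
#' the analysis window mark the record as having invalid data.
#'
#' @param stream Tibble with `time_ms`, `x_deg`, `y_deg` covering the trial
#'   from central onset (time 0) through distractor offset.
#' @param trial One schedule row with at least `distractor_side`; other
#'   fields (`block`, `stimulus_class`, `identity`, `expression`,
#'   `trial_index`, `infant_id`) are carried into the record.
#' @param soa_ms Central-to-distractor onset asynchrony (default 1000 ms).
#' @param analysis_window_ms Disengagement analysis window after distractor
#'   onset, default `c(150, 1000)`.
#' @param central_halfsize Half-extents (degrees) of the central area of
#'   interest, default `c(4.8, 5.1)`.
#' @param sample_rate Sampling rate in Hz; inferred from the stream's median
#'   sample spacing when `NULL`.
#' @return One-row tibble: trial metadata plus `central_fixation_prop`,
#'   `shift_latency_ms`, `shift_direction`
#'   (`toward_distractor`/`away`/`none`), `data_valid`, `disengaged`.
#' @export
code_trial <- function(stream, trial, soa_ms = 1000,
                       analysis_window_ms = c(150, 1000),
                       central_halfsize = c(4.8, 5.1),
                       sample_rate = NULL) {
  ord <- order(stream$time_ms)
  tm <- stream$time_ms[ord]
  x <- stream$x_deg[ord]
  y <- stream$y_deg[ord]
  period <- if (is.null(sample_rate)) stats::median(diff(tm)) else 1000 / sample_rate

  in_central <- abs(x) <= central_halfsize[1] & abs(y) <= central_halfsize[2]

  pre <- tm < soa_ms
  central_prop <- if (any(pre)) mean(in_central[pre]) else NA_real_

  win_hi <- soa_ms + analysis_window_ms[2]
  win <- tm >= soa_ms & tm <= win_hi
  data_valid <- sum(win) >= 2 &&
    max(diff(tm[win])) <= 1.5 * period &&
    min(tm[win]) <= soa_ms + 1.5 * period

  post <- which(tm >= soa_ms)
  dep <- post[!in_central[post]]
  if (length(dep) == 0) {
    latency <- NA_real_
    direction <- "none"
  } else {
    j <- dep[1]
    latency <- tm[j] - soa_ms
    side_sign <- if (trial$distractor_side == "left") -1 else 1
    direction <- if (sign(x[j]) == side_sign && abs(x[j]) > central_halfsize[1]) {
      "toward_distractor"
    } else {
      "away"
    }
  }
  disengaged <- !is.na(latency) && direction == "toward_distractor" &&
    latency > analysis_window_ms[1] && latency <= analysis_window_ms[2]

  meta <- c(
    "infant_id", "block", "trial_index", "stimulus_class", "identity",
    "expression", "distractor_side"
  )
  rec <- tibble::as_tibble(as.list(trial)[intersect(meta, names(trial))])
  rec$central_fixation_prop <- central_prop
  rec$shift_latency_ms <- latency
  rec$shift_direction <- direction
  rec$data_valid <- data_valid
  rec$disengaged <- disengaged
  rec
}

#' Judge trial validity
#'
#' Applies the four inclusion criteria for video-coded disengagement trials,
#' in order: (i) fixation on the central stimulus for at least 75% of the
#' pre-distractor period; (ii) valid video data over the analysis period;
#' (iii) any gaze shift started strictly later than 150 ms after distractor
#' onset (not premature); (iv) any shift was directed toward the lateral
#' stimulus. `invalid_reason` names the first failed criterion.
#'
#' @param trials Trial records (one or more rows) as produced by
#'   [code_trial()] or [simulate_cohort()].
#' @param min_fixation Criterion (i) threshold, default 0.75.
#' @param premature_ms Criterion (iii) bound, default 150 ms (strict `>`).
#' @return `trials` with logical `valid` and character `invalid_reason`
#'   (`NA` for valid trials) columns appended.
#' @export
trial_validity <- function(trials, min_fixation = 0.75, premature_ms = 150) {
  ok_i <- !is.na(trials$central_fixation_prop) &
    trials$central_fixation_prop >= min_fixation
  ok_ii <- trials$data_valid
  ok_iii <- is.na(trials$shift_latency_ms) |
    trials$shift_latency_ms > premature_ms
  ok_iv <- trials$shift_direction != "away"

  reason <- rep(NA_character_, nrow(trials))
  reason[!ok_iv] <- "wrong_direction"
  reason[!ok_iii] <- "premature_shift"
  reason[!ok_ii] <- "invalid_data"
  reason[!ok_i] <- "insufficient_fixation"

  trials$valid <- ok_i & ok_ii & ok_iii & ok_iv
  trials$invalid_reason <- reason
  trials
}

#' Per-infant condition scores
#'
#' Aggregates validity-judged trials into each infant's probability of no
#' disengagement and mean dwell time for the four stimulus conditions
#' (parent/unfamiliar x face/non-face) and the pooled face and non-face
#' conditions. Facial expressions are averaged together. The probability is
#' the exact count ratio (valid trials without disengagement) / (valid
#' trials). Dwell time is the shift latency capped at the 1000-ms window end,
#' with 1000 ms assigned to no-disengagement trials (right-censoring at the
#' cap; see the package vignette).
#'
#' An infant is `included` when every condition has more than two (i.e. at
#' least `min_valid`) valid trials; with `pooling = "pooled2"` the rule is
#' applied to the pooled face and non-face conditions only.
#'
#' @param trials Trial records for one or more infants; [trial_validity()] is
#'   applied first when the `valid` column is missing.
#' @param min_valid Minimum valid trials per condition for inclusion
#'   (default 3, the ">2 valid trials" rule).
#' @param pooling `"split4"` (default) enforces the rule on all four
#'   identity-by-class conditions; `"pooled2"` on pooled face/non-face only.
#' @return Tibble, one row per infant: `nv_*` (valid-trial counts), `p_*`
#'   (no-disengagement probabilities), `dwell_*` (mean dwell, ms) for
#'   `parent_face`, `unfamiliar_face`, `parent_nonface`,
#'   `unfamiliar_nonface`, `face`, `nonface`; plus `included`.
#' @export
condition_scores <- function(trials, min_valid = 3,
                             pooling = c("split4", "pooled2")) {
  pooling <- match.arg(pooling)
  if (!"valid" %in% names(trials)) {
    trials <- trial_validity(trials)
  }
  if (!"infant_id" %in% names(trials)) {
    trials$infant_id <- "infant"
  }
  ids <- unique(trials$infant_id)

  v <- trials[trials$valid, , drop = FALSE]
  v$dwell <- ifelse(v$disengaged, pmin(v$shift_latency_ms, 1000), 1000)
  v$condition <- paste(v$identity, v$stimulus_class, sep = "_")

  summarise_by <- function(d, key) {
    dplyr::summarise(
      dplyr::group_by(d, .data$infant_id, .data[[key]]),
      nv = dplyr::n(),
      p = mean(!.data$disengaged),
      dwell = mean(.data$dwell),
      .groups = "drop"
    )
  }
  conds <- c(
    "parent_face", "unfamiliar_face", "parent_nonface", "unfamiliar_nonface"
  )
  by_cond <- summarise_by(v, "condition")
  by_cond$condition <- factor(by_cond$condition, levels = conds)
  by_class <- summarise_by(v, "stimulus_class")
  by_class$stimulus_class <- factor(by_class$stimulus_class,
    levels = c("face", "nonface")
  )

  w1 <- tidyr::pivot_wider(
    tidyr::complete(by_cond,
      infant_id = ids, condition = factor(conds, levels = conds),
      fill = list(nv = 0L)
    ),
    names_from = "condition", values_from = c("nv", "p", "dwell"),
    names_glue = "{.value}_{condition}"
  )
  w2 <- tidyr::pivot_wider(
    tidyr::complete(by_class,
      infant_id = ids,
      stimulus_class = factor(c("face", "nonface"), levels = c("face", "nonface")),
      fill = list(nv = 0L)
    ),
    names_from = "stimulus_class", values_from = c("nv", "p", "dwell"),
    names_glue = "{.value}_{stimulus_class}"
  )
  out <- dplyr::left_join(w1, w2, by = "infant_id")

  if (pooling == "split4") {
    nv_cols <- paste0("nv_", conds)
  } else {
    nv_cols <- c("nv_face", "nv_nonface")
  }
  out$included <- Reduce(`&`, lapply(out[nv_cols], function(x) x >= min_valid))
  out[match(ids, out$infant_id), , drop = FALSE]
}
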