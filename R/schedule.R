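#' Generate a randomized disengagement-test trial schedule
#'
#' Builds the 48-trial schedule of the overlap (disengagement) paradigm:
#' four 12-trial blocks, each containing six face and six non-face trials in
#' randomized order. Parent identity is used in blocks 2 and 3, unfamiliar
#' adult identity in blocks 1 and 4. Within every block the lateral distractor
#' appears equally often on the left and the right side separately for the
#' face and the non-face trials (3/3 each), which also balances sides across
#' the block. Face trials cycle through neutral, happy, and fearful
#' expressions (two of each per block); each non-face pattern inherits the
#' expression of its source face.
#'
#' The central stimulus is shown for a 1000-ms onset asynchrony before the
#' distractor, which stays on for 2000 ms; the disengagement analysis window
#' is 150--1000 ms after distractor onset. These constants are attached as
#' attributes (`soa_ms`, `distractor_duration_ms`, `analysis_window_ms`).
#'
#' @param seed Optional integer; when supplied the schedule is drawn under a
#'   local RNG seed (the ambient RNG state is untouched).
#' @return A tibble of class `trial_schedule` with columns `block`,
#'   `trial_index` (1--48), `stimulus_class` (`face`/`nonface`), `identity`
#'   (`parent`/`unfamiliar`), `expression`, `distractor_side`.
#' @examples
#' sched <- generate_trial_schedule(seed = 1)
#' table(sched$block, sched$stimulus_class)
#' @export
generate_trial_schedule <- function(seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_trial_schedule()))
  }
  one_block <- function(b) {
    cls <- sample(rep(c("face", "nonface"), 6L))
    side <- character(12L)
    side[cls == "face"] <- sample(rep(c("left", "right"), 3L))
    side[cls == "nonface"] <- sample(rep(c("left", "right"), 3L))
    expr <- character(12L)
    expr[cls == "face"] <- sample(rep(c("neutral", "happy", "fearful"), 2L))
    expr[cls == "nonface"] <- sample(rep(c("neutral", "happy", "fearful"), 2L))
    data.frame(
      block = b,
      stimulus_class = cls,
      identity = if (b %in% c(2L, 3L)) "parent" else "unfamiliar",
      expression = expr,
      distractor_side = side,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(1:4, one_block))
  out$trial_index <- seq_len(48L)
  out <- tibble::as_tibble(
    out[, c(
      "block", "trial_index", "stimulus_class", "identity",
      "expression", "distractor_side"
    )]
  )
  attr(out, "soa_ms") <- 1000
  attr(out, "distractor_duration_ms") <- 2000
  attr(out, "analysis_window_ms") <- c(150, 1000)
  class(out) <- c("trial_schedule", class(out))
  out
}
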