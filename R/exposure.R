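#' Clip presence intervals to a daily time window
#'
#' Restricts every interval to the active-care window of its day (by default
#' 07:00--22:00). Intervals spanning midnight are split at day boundaries
#' before clipping, so each returned interval lies entirely within the window
#' of a single day. Intervals are half-open `[start, end)` at minute
#' resolution.
#'
#' @param intervals Data frame with `start` and `end` columns (POSIXct, or
#'   numeric minutes since an epoch midnight); other columns are carried
#'   through.
#' @param daily_window Length-2 vector of clock times (`"HH:MM"` strings or
#'   minutes past midnight) giving the window start and end within one day.
#' @return A tibble with the same columns; every row lies within the daily
#'   window, and the total clipped duration never exceeds the original.
#' @examples
#' d <- tibble::tibble(
#'   start = as.POSIXct("2020-01-01 06:30", tz = "UTC"),
#'   end = as.POSIXct("2020-01-01 08:00", tz = "UTC")
#' )
#' clip_to_window(d) # 07:00--08:00
#' @export
clip_to_window <- function(intervals, daily_window = c("07:00", "22:00")) {
  ws <- parse_clock(daily_window[1])
  we <- parse_clock(daily_window[2])
  stopifnot(ws < we, we <= .MIN_PER_DAY)
  if (nrow(intervals) == 0) {
    return(tibble::as_tibble(intervals))
  }
  s <- as_minutes(intervals$start)
  e <- as_minutes(intervals$end)
  bad <- which(!(s < e) | is.na(s) | is.na(e))
  if (length(bad) > 0) {
    stop(
      "invalid presence interval (start >= end or missing) at row(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  first_day <- floor(s / .MIN_PER_DAY)
  last_day <- floor((e - 1e-9) / .MIN_PER_DAY)
  n_pieces <- last_day - first_day + 1L
  idx <- rep.int(seq_along(s), n_pieces)
  day <- unlist(Map(seq, first_day, last_day), use.names = FALSE)
  ps <- pmax(s[idx], day * .MIN_PER_DAY + ws)
  pe <- pmin(e[idx], day * .MIN_PER_DAY + we)
  keep <- ps < pe
  out <- tibble::as_tibble(intervals[idx[keep], , drop = FALSE])
  out$start <- restore_time(ps[keep], intervals$start)
  out$end <- restore_time(pe[keep], intervals$end)
  out
}

#' Total presence hours for one infant
#'
#' Sums the durations of a set of presence intervals, in hours, after merging
#' overlaps. Intervals are expected to be clipped to the daily window first
#' (see [clip_to_window()]); over a 14-day diary this gives the presence-hours
#' factor of the speech-exposure composite.
#'
#' @param intervals Data frame of intervals for a single infant, with `start`,
#'   `end`, and optionally `parent_role` columns.
#' @param parent_role Optional; restrict to `"mother"` or `"father"` rows.
#' @return Total hours (scalar); 0 for an empty set.
#' @export
presence_hours <- function(intervals, parent_role = NULL) {
  if (!is.null(parent_role) && "parent_role" %in% names(intervals)) {
    intervals <- intervals[intervals$parent_role == parent_role, , drop = FALSE]
  }
  if (nrow(intervals) == 0) {
    return(0)
  }
  if ("infant_id" %in% names(intervals) &&
    length(unique(intervals$infant_id)) > 1) {
    stop("presence_hours expects intervals for a single infant", call. = FALSE)
  }
  m <- normalize_intervals(intervals)
  sum(as_minutes(m$end) - as_minutes(m$start)) / 60
}

#' Observed word frequency for one parent on the recording day
#'
#' Computes the parent's words per hour while present: adult words from the
#' parent's sex channel (mother: female words, father: male words), summed
#' over audio segments that overlap the parent's presence intervals, divided
#' by the presence hours during the recording. Words in a segment that only
#' partially overlaps presence are apportioned proportionally to the overlap
#' fraction of the segment duration (uniform within-segment word rate).
#'
#' @param segments Data frame with `start` (POSIXct or minutes), `duration_s`,
#'   `female_words`, `male_words`; one infant's recording day.
#' @param presence Data frame of the same infant's presence intervals on the
#'   recording day, already clipped to the daily window, with `parent_role`.
#' @param parent_role `"mother"` or `"father"`.
#' @return Words per hour, or `NA_real_` when the parent has zero presence
#'   during the recording day (the imputation path).
#' @export
observed_word_frequency <- function(segments, presence, parent_role) {
  parent_role <- match.arg(parent_role, c("mother", "father"))
  pres <- presence
  if ("parent_role" %in% names(pres)) {
    pres <- pres[pres$parent_role == parent_role, , drop = FALSE]
  }
  hrs <- presence_hours(pres)
  if (hrs <= 0) {
    return(NA_real_)
  }
  if (nrow(segments) == 0) {
    return(0)
  }
  pres <- normalize_intervals(pres)
  ss <- as_minutes(segments$start)
  se <- ss + segments$duration_s / 60
  words <- if (parent_role == "mother") segments$female_words else segments$male_words
  ov <- overlap_minutes(ss, se, as_minutes(pres$start), as_minutes(pres$end))
  sum(words * ov / (se - ss)) / hrs
}

#' Impute missing word frequencies across a cohort
#'
#' Applies the study's precedence rules to parents with no presence during
#' their infant's recording day (observed frequency `NA`):
#' 1. single-parent family and `parent_role == "father"`: frequency 0
#'    (`single_parent_zero`);
#' 2. the co-twin's recording has this parent observed: the co-twin's value
#'    (`twin_cosample`);
#' 3. otherwise the site-specific median of observed frequencies for that
#'    role (`site_median`).
#'
#' @param frequencies Tibble with one row per infant x parent role:
#'   `infant_id`, `parent_role`, `word_frequency` (`NA` where unobserved).
#' @param infants Infant table with `infant_id`, `site`, `twin_pair_id`
#'   (`NA` for singletons), `single_parent` (logical).
#' @return `frequencies` with `word_frequency` filled in and a
#'   `frequency_source` column (`observed`, `single_parent_zero`,
#'   `twin_cosample`, or `site_median`).
#' @export
impute_word_frequency <- function(frequencies, infants) {
  d <- dplyr::left_join(
    frequencies,
    infants[, c("infant_id", "site", "twin_pair_id", "single_parent")],
    by = "infant_id"
  )
  d$frequency_source <- ifelse(is.na(d$word_frequency), NA_character_, "observed")

  site_medians <- dplyr::summarise(
    dplyr::group_by(d[!is.na(d$word_frequency), ], .data$site, .data$parent_role),
    site_median = stats::median(.data$word_frequency),
    .groups = "drop"
  )

  miss <- which(is.na(d$word_frequency))
  for (i in miss) {
    if (isTRUE(d$single_parent[i]) && d$parent_role[i] == "father") {
      d$word_frequency[i] <- 0
      d$frequency_source[i] <- "single_parent_zero"
      next
    }
    if (!is.na(d$twin_pair_id[i])) {
      co <- which(
        d$twin_pair_id == d$twin_pair_id[i] &
          d$infant_id != d$infant_id[i] &
          d$parent_role == d$parent_role[i] &
          d$frequency_source == "observed"
      )
      co <- co[!is.na(co) & !is.na(d$word_frequency[co])]
      if (length(co) == 1) {
        d$word_frequency[i] <- d$word_frequency[co]
        d$frequency_source[i] <- "twin_cosample"
        next
      }
    }
    m <- site_medians$site_median[
      site_medians$site == d$site[i] & site_medians$parent_role == d$parent_role[i]
    ]
    if (length(m) == 0) {
      stop(
        "cannot impute word frequency: no observed ", d$parent_role[i],
        " frequencies at site ", d$site[i],
        call. = FALSE
      )
    }
    d$word_frequency[i] <- m
    d$frequency_source[i] <- "site_median"
  }
  d[, c(names(frequencies), "frequency_source")]
}

#' Speech-exposure composite
#'
#' `exposure words = word frequency (words/hour) x presence hours over the
#' 14-day diary`. Both inputs must be non-negative; the result is a
#' word-count-like quantity (words per 14 days).
#'
#' @param word_frequency Words per hour (vectorised).
#' @param presence_hours_14d Presence hours over the diary period.
#' @return Numeric exposure in words.
#' @examples
#' compute_exposure(100, 14) # 1400
#' @export
compute_exposure <- function(word_frequency, presence_hours_14d) {
  if (any(word_frequency < 0, na.rm = TRUE) ||
    any(presence_hours_14d < 0, na.rm = TRUE)) {
    stop("word frequency and presence hours must be non-negative", call. = FALSE)
  }
  word_frequency * presence_hours_14d
}

#' Per-infant exposure table for a cohort
#'
#' End-to-end exposure computation: clips the diary and the audio segments to
#' the daily window, derives each parent's presence hours over the diary
#' period and their observed word frequency on the infant's recording day
#' (the day carrying audio segments), imputes missing frequencies with
#' [impute_word_frequency()], and multiplies frequency by presence. A
#' `total` row per infant sums the mother and father exposures.
#'
#' @param diary Presence diary: `infant_id`, `parent_role`, `start`, `end`.
#' @param segments Audio word-count segments: `infant_id`, `start`,
#'   `duration_s`, `female_words`, `male_words`.
#' @param infants Infant table (see [impute_word_frequency()]).
#' @param daily_window Daily clip window, default 07:00--22:00.
#' @return Tibble with one row per infant x role (`mother`, `father`,
#'   `total`): `word_frequency`, `frequency_source`, `presence_hours_14d`,
#'   `exposure_words`.
#' @export
exposure_table <- function(diary, segments, infants,
                           daily_window = c("07:00", "22:00")) {
  roles <- c("mother", "father")
  diary_c <- clip_to_window(diary, daily_window)
  diary_c$s <- as_minutes(diary_c$start)
  diary_c$e <- as_minutes(diary_c$end)

  # presence hours over the whole diary period, per infant x role
  grid <- tidyr::expand_grid(infant_id = infants$infant_id, parent_role = roles)
  pres14 <- dplyr::summarise(
    dplyr::group_by(diary_c, .data$infant_id, .data$parent_role),
    presence_hours_14d = sum(.data$e - .data$s) / 60,
    .groups = "drop"
  )
  pres14 <- dplyr::left_join(grid, pres14, by = c("infant_id", "parent_role"))
  pres14$presence_hours_14d[is.na(pres14$presence_hours_14d)] <- 0

  # each infant's recording day = the day its audio segments fall on
  seg <- segments
  seg$s <- as_minutes(seg$start)
  seg$e <- seg$s + seg$duration_s / 60
  rec_day <- dplyr::summarise(
    dplyr::group_by(seg, .data$infant_id),
    rec_day = floor(stats::median(.data$s) / .MIN_PER_DAY),
    .groups = "drop"
  )

  # recording-day presence (clipped) and overlap-apportioned words
  diary_rec <- dplyr::inner_join(diary_c, rec_day, by = "infant_id")
  diary_rec <- diary_rec[
    floor(diary_rec$s / .MIN_PER_DAY) == diary_rec$rec_day, ,
    drop = FALSE
  ]
  rec_hours <- dplyr::summarise(
    dplyr::group_by(diary_rec, .data$infant_id, .data$parent_role),
    rec_presence_hours = sum(.data$e - .data$s) / 60,
    .groups = "drop"
  )

  ov <- dplyr::inner_join(
    seg[, c("infant_id", "s", "e", "female_words", "male_words")],
    diary_rec[, c("infant_id", "parent_role", "s", "e")],
    by = "infant_id", suffix = c("_seg", "_pres"),
    relationship = "many-to-many"
  )
  ov$ov_min <- pmax(0, pmin(ov$e_seg, ov$e_pres) - pmax(ov$s_seg, ov$s_pres))
  ov$channel_words <- ifelse(ov$parent_role == "mother",
    ov$female_words, ov$male_words
  )
  words <- dplyr::summarise(
    dplyr::group_by(ov, .data$infant_id, .data$parent_role),
    words = sum(.data$channel_words * .data$ov_min / (.data$e_seg - .data$s_seg)),
    .groups = "drop"
  )

  freq <- dplyr::left_join(grid, rec_hours, by = c("infant_id", "parent_role"))
  freq <- dplyr::left_join(freq, words, by = c("infant_id", "parent_role"))
  freq$word_frequency <- ifelse(
    is.na(freq$rec_presence_hours) | freq$rec_presence_hours <= 0,
    NA_real_,
    ifelse(is.na(freq$words), 0, freq$words) / freq$rec_presence_hours
  )
  freq <- impute_word_frequency(
    freq[, c("infant_id", "parent_role", "word_frequency")], infants
  )

  out <- dplyr::left_join(freq, pres14, by = c("infant_id", "parent_role"))
  out$exposure_words <- compute_exposure(out$word_frequency, out$presence_hours_14d)

  totals <- dplyr::summarise(
    dplyr::group_by(out, .data$infant_id),
    parent_role = "total",
    word_frequency = NA_real_,
    frequency_source = NA_character_,
    presence_hours_14d = sum(.data$presence_hours_14d),
    exposure_words = sum(.data$exposure_words),
    .groups = "drop"
  )
  res <- dplyr::bind_rows(out, totals)
  dplyr::arrange(
    res,
    match(.data$infant_id, infants$infant_id),
    match(.data$parent_role, c("mother", "father", "total"))
  )
}
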