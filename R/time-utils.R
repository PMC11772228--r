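# Internal time representation: numeric minutes since 2020-01-01 00:00 UTC.
# All intervals are half-open [start, end) at minute resolution; day boundaries
# fall at multiples of 1440 minutes because the epoch is a UTC midnight.

.MIN_PER_DAY <- 1440
.EPOCH <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

as_minutes <- function(x) {
  if (inherits(x, "POSIXct")) {
    (as.numeric(x) - as.numeric(.EPOCH)) / 60
  } else if (is.numeric(x)) {
    x
  } else {
    stop("time columns must be POSIXct or numeric minutes", call. = FALSE)
  }
}

minutes_to_time <- function(m) .EPOCH + m * 60

# restore minutes to the same representation as a template column
restore_time <- function(m, template) {
  if (inherits(template, "POSIXct")) minutes_to_time(m) else m
}

# "07:00" -> 420 minutes past midnight
parse_clock <- function(x) {
  if (is.numeric(x)) {
    return(x)
  }
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.numeric(parts[1]) * 60 + ifelse(length(parts) > 1, as.numeric(parts[2]), 0)
}

#' Merge overlapping presence intervals
#'
#' Normalizes a set of half-open intervals so that, within each
#' `(infant_id, parent_role)` group, no two intervals overlap or touch.
#' Required before summing durations so overlapping diary entries are not
#' double counted.
#'
#' @param intervals A data frame with columns `start` and `end` (POSIXct or
#'   numeric minutes) and optionally `infant_id` and `parent_role`.
#' @return A tibble with the same time representation, columns `infant_id`,
#'   `parent_role` (when present), `start`, `end`, sorted and merged.
#' @export
normalize_intervals <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(tibble::as_tibble(intervals))
  }
  keys <- intersect(c("infant_id", "parent_role"), names(intervals))
  d <- tibble::tibble(
    s = as_minutes(intervals$start),
    e = as_minutes(intervals$end)
  )
  for (k in keys) d[[k]] <- intervals[[k]]
  d <- dplyr::arrange(d, dplyr::across(dplyr::all_of(c(keys, "s"))))
  d <- dplyr::group_by(d, dplyr::across(dplyr::all_of(keys)))
  d <- dplyr::mutate(d,
    run = cumsum(.data$s > dplyr::lag(cummax(.data$e), default = -Inf))
  )
  d <- dplyr::group_by(d, .data$run, .add = TRUE)
  d <- dplyr::summarise(d, s = min(.data$s), e = max(.data$e), .groups = "drop")
  res <- tibble::tibble(
    start = restore_time(d$s, intervals$start),
    end = restore_time(d$e, intervals$end)
  )
  for (k in rev(keys)) res <- dplyr::bind_cols(tibble::tibble(!!k := d[[k]]), res)
  res
}

# total overlap (minutes) of each [s1,e1) interval with a merged set [s2,e2)
overlap_minutes <- function(s1, e1, s2, e2) {
  if (length(s2) == 0) {
    return(rep(0, length(s1)))
  }
  ov <- outer(e1, e2, pmin) - outer(s1, s2, pmax)
  rowSums(pmax(ov, 0))
}
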