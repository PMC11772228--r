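# Brute-force oracles, deliberately independent of the package internals.
# All work at minute resolution on integer-minute fixtures.

MIN_DAY <- 1440

# minutes of [s, e) whose minute-of-day lies in [ws, we)
oracle_clip_minutes <- function(s, e, ws = 420, we = 1320) {
  total <- 0L
  for (i in seq_along(s)) {
    mins <- seq(s[i], e[i] - 1)
    total <- total + sum(mins %% MIN_DAY >= ws & mins %% MIN_DAY < we)
  }
  total
}

# union of clipped minutes across intervals (handles overlap)
oracle_minute_set <- function(s, e, ws = 420, we = 1320) {
  mins <- unlist(Map(function(a, b) seq(a, b - 1), s, e))
  mins <- mins[mins %% MIN_DAY >= ws & mins %% MIN_DAY < we]
  unique(mins)
}

oracle_presence_hours <- function(s, e, ws = 420, we = 1320) {
  length(oracle_minute_set(s, e, ws, we)) / 60
}

# per-minute word apportionment: each segment spreads its words uniformly over
# its minutes; minutes inside the (clipped) presence set contribute
oracle_word_frequency <- function(seg_start, seg_dur_min, words,
                                  pres_s, pres_e, ws = 420, we = 1320) {
  pset <- oracle_minute_set(pres_s, pres_e, ws, we)
  hrs <- length(pset) / 60
  if (hrs == 0) {
    return(NA_real_)
  }
  tot <- 0
  for (i in seq_along(seg_start)) {
    mins <- seq(seg_start[i], seg_start[i] + seg_dur_min[i] - 1)
    tot <- tot + words[i] * sum(mins %in% pset) / seg_dur_min[i]
  }
  tot / hrs
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# minutes since 2020-01-01 00:00 UTC -> POSIXct (the simulator's epoch)
minutes_to_time_test <- function(m) {
  as.POSIXct("2020-01-01 00:00:00", tz = "UTC") + m * 60
}

# random integer-minute intervals within the first `days` days
random_intervals <- function(n, days = 3) {
  s <- sample.int(days * MIN_DAY - 2L, n, replace = TRUE)
  len <- sample.int(600L, n, replace = TRUE)
  e <- pmin(s + len, days * MIN_DAY)
  tibble::tibble(start = as.numeric(s), end = as.numeric(e))
}
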