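# exposure module: window clipping, presence, word frequency, imputation

test_that("clip_to_window clips boundaries and splits midnight spans", {
  # 06:30-08:00 -> 07:00-08:00
  d <- tibble::tibble(start = 390, end = 480)
  out <- clip_to_window(d)
  expect_equal(out$start, 420)
  expect_equal(out$end, 480)
  # 21:00-23:00 -> 21:00-22:00
  d <- tibble::tibble(start = 1260, end = 1380)
  out <- clip_to_window(d)
  expect_equal(c(out$start, out$end), c(1260, 1320))
  # 21:00 day 1 - 08:00 day 2 splits into two clipped pieces
  d <- tibble::tibble(start = 1260, end = MIN_DAY + 480)
  out <- clip_to_window(d)
  expect_equal(nrow(out), 2L)
  expect_equal(out$start, c(1260, MIN_DAY + 420))
  expect_equal(out$end, c(1320, MIN_DAY + 480))
  # POSIXct representation round-trips
  d <- tibble::tibble(
    start = as.POSIXct("2020-01-01 06:30", tz = "UTC"),
    end = as.POSIXct("2020-01-01 08:00", tz = "UTC")
  )
  out <- clip_to_window(d)
  expect_s3_class(out$start, "POSIXct")
  expect_equal(format(out$start, "%H:%M", tz = "UTC"), "07:00")
})

test_that("clip_to_window rejects malformed intervals naming the row", {
  d <- tibble::tibble(start = c(100, 500), end = c(200, 400))
  expect_error(clip_to_window(d), "row\\(s\\): 2")
})

test_that("clipped totals equal the minute-resolution oracle on random intervals", {
  withr::with_seed(11, {
    d <- random_intervals(50)
    out <- clip_to_window(d)
    expect_equal(sum(out$end - out$start), oracle_clip_minutes(d$start, d$end))
  })
})

test_that("presence_hours handles empty, regular, and overlapping diaries", {
  expect_equal(presence_hours(tibble::tibble(start = numeric(), end = numeric())), 0)
  # 14 days x 8 h/day
  d <- tibble::tibble(
    start = (0:13) * MIN_DAY + 480,
    end = (0:13) * MIN_DAY + 960
  )
  expect_equal(presence_hours(d), 112)
  # overlapping intervals are not double counted
  d <- tibble::tibble(start = c(480, 500), end = c(600, 700))
  expect_equal(presence_hours(d), (700 - 480) / 60)
  withr::with_seed(12, {
    r <- clip_to_window(random_intervals(30))
    expect_equal(
      presence_hours(r),
      oracle_presence_hours(r$start, r$end)
    )
  })
})

test_that("observed_word_frequency matches the per-minute apportionment oracle", {
  pres <- tibble::tibble(parent_role = "mother", start = 480, end = 600) # 2 h
  segs <- tibble::tibble(
    start = c(480, 540), duration_s = c(3600, 3600),
    female_words = c(0, 0), male_words = c(10, 20)
  )
  expect_equal(observed_word_frequency(segs, pres, "mother"), 0)
  # absent parent -> NA (imputation path)
  expect_equal(
    observed_word_frequency(segs, pres[0, ], "father"),
    NA_real_
  )
  withr::with_seed(13, {
    for (rep in 1:5) {
      pres <- clip_to_window(random_intervals(4))
      pres$parent_role <- "mother"
      ns <- 12
      segs <- tibble::tibble(
        start = as.numeric(sample.int(MIN_DAY - 10, ns)),
        duration_s = sample(c(300, 600, 900), ns, replace = TRUE),
        female_words = sample(0:80, ns, replace = TRUE),
        male_words = sample(0:30, ns, replace = TRUE)
      )
      got <- observed_word_frequency(segs, pres, "mother")
      want <- oracle_word_frequency(
        segs$start, segs$duration_s / 60, segs$female_words,
        pres$start, pres$end
      )
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("imputation follows the single-parent / co-twin / site-median precedence", {
  infants <- tibble::tibble(
    infant_id = c("I1", "I2", "I3", "I4", "I5", "I6"),
    site = c("A", "A", "A", "A", "B", "B"),
    twin_pair_id = c(NA, "T1", "T1", NA, NA, NA),
    single_parent = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  freqs <- tibble::tibble(
    infant_id = rep(infants$infant_id, each = 2),
    parent_role = rep(c("mother", "father"), 6),
    word_frequency = c(
      900, NA, # I1: single mother, father absent -> 0
      800, NA, # I2: twin, father absent -> co-twin value
      700, 320, # I3: co-twin observed father
      NA, 100, # I4: mother absent -> site A median of {900,800,700}
      250, 10, # I5, I6: site B observed
      NA, 14 # I6 mother absent -> site B median = 250
    )
  )
  out <- impute_word_frequency(freqs, infants)
  get <- function(id, role) {
    out[out$infant_id == id & out$parent_role == role, ]
  }
  expect_equal(get("I1", "father")$word_frequency, 0)
  expect_equal(get("I1", "father")$frequency_source, "single_parent_zero")
  expect_equal(get("I2", "father")$word_frequency, 320)
  expect_equal(get("I2", "father")$frequency_source, "twin_cosample")
  expect_equal(get("I4", "mother")$word_frequency, 800)
  expect_equal(get("I4", "mother")$frequency_source, "site_median")
  expect_equal(get("I6", "mother")$word_frequency, 250)
  expect_true(all(out$frequency_source[!is.na(freqs$word_frequency)] == "observed"))
  # median example {100, 250, 400} -> 250
  inf2 <- tibble::tibble(
    infant_id = paste0("J", 1:4), site = "A",
    twin_pair_id = NA_character_, single_parent = FALSE
  )
  fr2 <- tibble::tibble(
    infant_id = paste0("J", 1:4), parent_role = "mother",
    word_frequency = c(100, 250, 400, NA)
  )
  expect_equal(impute_word_frequency(fr2, inf2)$word_frequency[4], 250)
  # no observed frequencies for a role at a site -> error
  fr3 <- tibble::tibble(
    infant_id = paste0("J", 1:4), parent_role = "father",
    word_frequency = NA_real_
  )
  expect_error(impute_word_frequency(fr3, inf2), "cannot impute")
})

test_that("compute_exposure is the exact product and rejects negatives", {
  expect_equal(compute_exposure(0, 100), 0)
  expect_equal(compute_exposure(100, 14), 1400)
  expect_error(compute_exposure(-1, 5), "non-negative")
})

test_that("exposure is monotone, scale-equivariant, and window-invariant", {
  withr::with_seed(14, {
    cfg <- simulation_config(
      n_infants_per_site = c(a = 3, b = 3),
      n_twin_pairs = 1, seed = 21
    )
    co <- simulate_cohort(cfg)
    ex <- exposure_table(co$diary, co$segments, co$infants)

    # adding a presence interval never decreases presence hours
    extra <- tibble::tibble(
      infant_id = co$infants$infant_id[1], parent_role = "mother",
      start = minutes_to_time_test(2 * MIN_DAY + 600),
      end = minutes_to_time_test(2 * MIN_DAY + 700),
      modality = "present"
    )
    ex2 <- exposure_table(
      dplyr::bind_rows(co$diary, extra), co$segments, co$infants
    )
    expect_true(all(ex2$presence_hours_14d >= ex$presence_hours_14d - 1e-9))

    # doubling all word counts doubles observed exposures exactly
    seg2 <- co$segments
    seg2$female_words <- 2L * seg2$female_words
    seg2$male_words <- 2L * seg2$male_words
    ex3 <- exposure_table(co$diary, seg2, co$infants)
    obs <- ex$frequency_source %in% "observed"
    expect_equal(
      ex3$exposure_words[obs], 2 * ex$exposure_words[obs],
      tolerance = 1e-12
    )

    # segments entirely outside 07:00-22:00 never affect any output
    outside <- tibble::tibble(
      infant_id = co$infants$infant_id,
      start = minutes_to_time_test((cfg$recording_day - 1) * MIN_DAY + 120),
      duration_s = 1800,
      female_words = 500L, male_words = 500L
    )
    ex4 <- exposure_table(
      co$diary, dplyr::bind_rows(co$segments, outside), co$infants
    )
    expect_equal(ex4$exposure_words, ex$exposure_words, tolerance = 1e-12)
  })
})

test_that("cohort exposure equals the minute-resolution oracle end to end", {
  cfg <- simulation_config(
    n_infants_per_site = c(a = 5, b = 5), n_twin_pairs = 2,
    p_parent_absent_recording_day = c(mother = 0.2, father = 0.4),
    p_single_parent = 0.2, seed = 31
  )
  co <- simulate_cohort(cfg)
  ex <- exposure_table(co$diary, co$segments, co$infants)

  diary_min <- co$diary
  diary_min$s <- as.numeric(diary_min$start - as.POSIXct("2020-01-01", tz = "UTC"),
    units = "mins"
  )
  diary_min$e <- as.numeric(diary_min$end - as.POSIXct("2020-01-01", tz = "UTC"),
    units = "mins"
  )
  seg_min <- co$segments
  seg_min$s <- as.numeric(seg_min$start - as.POSIXct("2020-01-01", tz = "UTC"),
    units = "mins"
  )
  rec_day <- floor(median(seg_min$s) / MIN_DAY)

  oracle_freq <- list()
  for (id in co$infants$infant_id) {
    for (role in c("mother", "father")) {
      dd <- diary_min[diary_min$infant_id == id & diary_min$parent_role == role, ]
      dd_rec <- dd[floor(dd$s / MIN_DAY) == rec_day, ]
      sg <- seg_min[seg_min$infant_id == id, ]
      words <- if (role == "mother") sg$female_words else sg$male_words
      f <- if (nrow(dd_rec) == 0) {
        NA_real_
      } else {
        oracle_word_frequency(
          sg$s, sg$duration_s / 60, words, dd_rec$s, dd_rec$e
        )
      }
      h <- if (nrow(dd) == 0) 0 else oracle_presence_hours(dd$s, dd$e)
      oracle_freq[[paste(id, role)]] <- c(freq = f, hours = h)
    }
  }
  for (key in names(oracle_freq)) {
    parts <- strsplit(key, " ")[[1]]
    row <- ex[ex$infant_id == parts[1] & ex$parent_role == parts[2], ]
    o <- oracle_freq[[key]]
    expect_equal(row$presence_hours_14d, unname(o["hours"]), tolerance = 1e-9)
    if (!is.na(o["freq"])) {
      expect_equal(row$word_frequency, unname(o["freq"]), tolerance = 1e-9)
      expect_equal(row$exposure_words, unname(o["freq"] * o["hours"]),
        tolerance = 1e-9
      )
    }
  }
  # total rows are the mother + father sum
  tot <- ex[ex$parent_role == "total", ]
  mf <- dplyr::summarise(
    dplyr::group_by(ex[ex$parent_role != "total", ], infant_id),
    s = sum(exposure_words)
  )
  expect_equal(tot$exposure_words, mf$s[match(tot$infant_id, mf$infant_id)])
})
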