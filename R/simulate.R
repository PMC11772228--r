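#' Configuration for the synthetic cohort simulator
#'
#' Collects and validates every parameter of the synthetic study generator.
#' Defaults emulate the magnitudes of a two-site very-preterm cohort cared
#' for in family-centred units: site A resembles a single-family-room unit
#' (high parental word frequency and presence), site B an open-bay unit with
#' markedly lower paternal presence. A latent bivariate-normal copula couples
#' each infant's log speech exposure to the trait driving face preference,
#' giving direct control of the injected rank correlation.
#'
#' @param n_infants_per_site Named length-2 vector, infants at sites `a`, `b`.
#' @param n_twin_pairs Number of complete twin pairs (both members enrolled);
#'   pairs are allocated to sites proportionally to site size.
#' @param rho_exposure_preference Latent correlation in `[-1, 1]` between the
#'   exposure normal score and the face-preference trait.
#' @param site_word_freq_params Log-normal `meanlog`/`sdlog` per site per
#'   parent role, words per hour while present.
#' @param site_presence_params Median daily presence hours (within the 15-h
#'   07:00--22:00 window) per site per role; daily hours follow a
#'   logistic-normal around the median.
#' @param presence_logit_sd Between-infant SD of daily presence on the logit
#'   (fraction-of-window) scale.
#' @param p_parent_absent_recording_day Named probabilities (`mother`,
#'   `father`) of a parent being absent for the whole recording day.
#' @param p_single_parent Probability that a family is a single-mother
#'   family (the father never appears in the diary or recording).
#' @param base_no_disengage Named probabilities (`face`, `nonface`) of no
#'   disengagement on a valid trial for an infant with trait 0.
#' @param trait_effect Log-odds change in face-trial no-disengagement per SD
#'   of the latent trait; non-face trials are unaffected by the trait.
#' @param general_attention_sd SD (log-odds) of an infant-level general
#'   disengagement tendency shared by the face and non-face conditions,
#'   independent of the trait; this is what the face-given-non-face
#'   adjustment in the analysis removes.
#' @param trial_invalid_rate Mean per-trial probability that coding fails one
#'   of the validity criteria; varies between infants (beta-distributed with
#'   concentration `trial_invalid_kappa`).
#' @param trial_invalid_kappa Concentration of the per-infant invalidity
#'   rate; larger values mean less between-infant variation.
#' @param gaze_noise_sd Gaussian positional noise of gaze samples, degrees of
#'   visual angle (stream mode).
#' @param sample_rate Gaze sampling rate in Hz (video coding: 30).
#' @param emit_gaze_streams If `TRUE`, raw 30-Hz gaze streams are generated
#'   alongside the trial table (slower; off by default).
#' @param exposure_loading Named loadings (`word`, `presence`) of the latent
#'   exposure score on log word frequency and logit daily presence.
#' @param twin_icc Intra-pair correlation of the latent exposure score.
#' @param background_words_per_hour Named (`female`, `male`) staff-speech
#'   word rates present regardless of parental presence.
#' @param segment_minutes Audio segment length in minutes (word-count export
#'   granularity).
#' @param n_days Diary length in days.
#' @param recording_day Diary day (1-based) on which the 16-h audio recording
#'   is made.
#' @param latency_meanlog,latency_sdlog Log-normal parameters of
#'   disengagement latency (ms), truncated to the 150--1000 ms analysis
#'   window. The latency distribution is an explicit modelling assumption.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output tables.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_infants_per_site = c(a = 25L, b = 38L),
    n_twin_pairs = 7L,
    rho_exposure_preference = 0.35,
    site_word_freq_params = list(
      a = list(
        mother = c(meanlog = log(1100), sdlog = 0.7),
        father = c(meanlog = log(330), sdlog = 0.9)
      ),
      b = list(
        mother = c(meanlog = log(230), sdlog = 0.7),
        father = c(meanlog = log(14), sdlog = 1.1)
      )
    ),
    site_presence_params = list(
      a = c(mother = 8, father = 4),
      b = c(mother = 12.5, father = 1)
    ),
    presence_logit_sd = 0.8,
    p_parent_absent_recording_day = c(mother = 0.02, father = 0.20),
    p_single_parent = 0.05,
    base_no_disengage = c(face = 0.55, nonface = 0.24),
    trait_effect = 1.0,
    general_attention_sd = 0.7,
    trial_invalid_rate = 0.2,
    trial_invalid_kappa = 6,
    gaze_noise_sd = 0.5,
    sample_rate = 30,
    emit_gaze_streams = FALSE,
    exposure_loading = c(word = 0.9, presence = 0.7),
    twin_icc = 0.8,
    background_words_per_hour = c(female = 25, male = 10),
    segment_minutes = 5,
    n_days = 14L,
    recording_day = 7L,
    latency_meanlog = log(400),
    latency_sdlog = 0.5,
    seed = 1L) {
  cfg <- list(
    n_infants_per_site = n_infants_per_site,
    n_twin_pairs = as.integer(n_twin_pairs),
    rho_exposure_preference = rho_exposure_preference,
    site_word_freq_params = site_word_freq_params,
    site_presence_params = site_presence_params,
    presence_logit_sd = presence_logit_sd,
    p_parent_absent_recording_day = p_parent_absent_recording_day,
    p_single_parent = p_single_parent,
    base_no_disengage = base_no_disengage,
    trait_effect = trait_effect,
    general_attention_sd = general_attention_sd,
    trial_invalid_rate = trial_invalid_rate,
    trial_invalid_kappa = trial_invalid_kappa,
    gaze_noise_sd = gaze_noise_sd,
    sample_rate = sample_rate,
    emit_gaze_streams = emit_gaze_streams,
    exposure_loading = exposure_loading,
    twin_icc = twin_icc,
    background_words_per_hour = background_words_per_hour,
    segment_minutes = segment_minutes,
    n_days = as.integer(n_days),
    recording_day = as.integer(recording_day),
    latency_meanlog = latency_meanlog,
    latency_sdlog = latency_sdlog,
    seed = as.integer(seed)
  )
  probs <- c(
    p_parent_absent_recording_day, p_single_parent, base_no_disengage,
    trial_invalid_rate
  )
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(rho_exposure_preference) > 1) {
    stop("configuration error: rho_exposure_preference must lie in [-1, 1]",
      call. = FALSE
    )
  }
  if (sample_rate <= 0) {
    stop("configuration error: sample_rate must be positive", call. = FALSE)
  }
  if (any(n_infants_per_site < 1) ||
    2L * cfg$n_twin_pairs > sum(n_infants_per_site)) {
    stop("configuration error: infant counts incompatible with twin pairs",
      call. = FALSE
    )
  }
  if (gaze_noise_sd < 0 || general_attention_sd < 0 ||
    twin_icc < 0 || twin_icc > 1 ||
    any(exposure_loading < -1 | exposure_loading > 1)) {
    stop("configuration error: invalid distribution parameters", call. = FALSE)
  }
  if (cfg$recording_day < 1 || cfg$recording_day > cfg$n_days) {
    stop("configuration error: recording_day outside the diary period",
      call. = FALSE
    )
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a complete synthetic cohort
#'
#' Generates every input the analysis pipeline consumes: an infant/covariate
#' table, a 14-day caregiver presence diary, word-count audio segments for
#' each infant's recording day, and coded eye-tracking trials (or raw gaze
#' streams when `emit_gaze_streams` is on), together with the ground-truth
#' latent variables.
#'
#' Each infant carries a latent exposure score `z` (twins share a
#' family-level component with intra-pair correlation `twin_icc`) and a
#' face-preference trait `t` with `cor(z, t) = rho_exposure_preference`.
#' `z` loads on the parents' log word frequency and logit daily presence, so
#' the realized log speech exposure and the trait share the injected
#' correlation up to measurement noise. Face-trial no-disengagement follows
#' `logit(p) = logit(base_face) + trait_effect * t`; non-face trials use the
#' base rate only.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort` with elements `infants`,
#'   `diary`, `segments`, `trials`, optionally `gaze_streams`, and
#'   `ground_truth` (config and per-infant latent variables).
#' @examples
#' cohort <- simulate_cohort(simulation_config(
#'   n_infants_per_site = c(a = 4, b = 4), n_twin_pairs = 1, seed = 1
#' ))
#' names(cohort)
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_a <- cfg$n_infants_per_site[["a"]]
  n_b <- cfg$n_infants_per_site[["b"]]
  n <- n_a + n_b
  pairs_a <- min(round(cfg$n_twin_pairs * n_a / n), floor(n_a / 2))
  pairs_b <- cfg$n_twin_pairs - pairs_a
  if (2 * pairs_b > n_b) {
    pairs_b <- floor(n_b / 2)
    pairs_a <- cfg$n_twin_pairs - pairs_b
  }

  site <- c(rep("a", n_a), rep("b", n_b))
  # first 2*pairs infants at each site form the twin pairs
  fam_local <- c(
    c(rep(seq_len(pairs_a), each = 2), seq_len(n_a - 2 * pairs_a) + pairs_a),
    c(rep(seq_len(pairs_b), each = 2), seq_len(n_b - 2 * pairs_b) + pairs_b) + n_a
  )
  family_id <- sprintf("F%03d", match(paste(site, fam_local), unique(paste(site, fam_local))))
  is_twin <- duplicated(family_id) | duplicated(family_id, fromLast = TRUE)
  twin_pair_id <- ifelse(is_twin, paste0("T", substr(family_id, 2, 4)), NA_character_)
  infant_id <- sprintf("I%03d", seq_len(n))

  n_fam <- length(unique(family_id))
  fam_idx <- match(family_id, unique(family_id))

  # latent exposure score (family-shared for twins) and face-preference trait
  g_fam <- rnorm(n_fam)
  z <- sqrt(cfg$twin_icc) * g_fam[fam_idx] + sqrt(1 - cfg$twin_icc) * rnorm(n)
  rho <- cfg$rho_exposure_preference
  trait <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  attention <- cfg$general_attention_sd * rnorm(n)

  single_parent <- (rbinom(n_fam, 1, cfg$p_single_parent) == 1)[fam_idx]

  # covariates (independent of the latent trait; null covariates by design)
  ga <- pmin(pmax(rnorm(n, 28.2, 2.1), 23.5), 31.9)
  ga[is_twin] <- ave(ga, family_id, FUN = function(x) x[1])[is_twin]
  birth_weight <- pmax(round(1100 + 170 * (ga - 28.2) + rnorm(n, 0, 150)), 450)
  sex <- ifelse(runif(n) < ifelse(site == "a", 0.72, 0.55), "male", "female")
  delivery <- ifelse(runif(n) < 0.57, "cesarean", "vaginal")
  delivery[is_twin] <- ave(delivery, family_id, FUN = function(x) x[1])[is_twin]
  edu_probs <- list(a = c(0.08, 0.12, 0.32, 0.48), b = c(0.21, 0.29, 0.08, 0.42))
  maternal_education <- vapply(
    site,
    function(s) sample.int(4L, 1L, prob = edu_probs[[s]]),
    integer(1)
  )
  maternal_education <- ave(maternal_education, family_id, FUN = function(x) x[1])

  infants <- tibble::tibble(
    infant_id = infant_id,
    site = toupper(site),
    family_id = family_id,
    twin_pair_id = twin_pair_id,
    single_parent = single_parent,
    sex = sex,
    gestational_age_weeks = round(ga, 1),
    birth_weight_g = birth_weight,
    delivery = delivery,
    maternal_education = as.integer(maternal_education)
  )

  # parental word frequency (words/h while present), family-correlated via z
  lw <- cfg$exposure_loading[["word"]]
  wf <- sapply(c("mother", "father"), function(role) {
    p <- t(vapply(site, function(s) cfg$site_word_freq_params[[s]][[role]], numeric(2)))
    exp(p[, 1] + p[, 2] * (lw * z + sqrt(1 - lw^2) * rnorm(n)))
  })

  # daily presence hours within the 07:00-22:00 window, logistic-normal
  lp <- cfg$exposure_loading[["presence"]]
  window_h <- 15
  pres_mu <- sapply(c("mother", "father"), function(role) {
    med <- vapply(site, function(s) cfg$site_presence_params[[s]][[role]], numeric(1))
    qlogis(med / window_h) +
      cfg$presence_logit_sd * (lp * z + sqrt(1 - lp^2) * rnorm(n))
  })

  absent_rec <- sapply(c("mother", "father"), function(role) {
    rbinom(n, 1, cfg$p_parent_absent_recording_day[[role]]) == 1
  })

  n_days <- cfg$n_days
  diary <- lapply(c("mother", "father"), function(role) {
    keep <- if (role == "father") !single_parent else rep(TRUE, n)
    idx <- rep(which(keep), each = n_days)
    day <- rep(seq_len(n_days), sum(keep))
    hrs <- window_h * plogis(pres_mu[idx, role] + rnorm(length(idx), 0, 0.5))
    drop <- day == cfg$recording_day & absent_rec[idx, role]
    idx <- idx[!drop]
    day <- day[!drop]
    hrs <- hrs[!drop]
    start_min <- (day - 1) * .MIN_PER_DAY + 420 +
      runif(length(idx)) * pmax(0, 900 - hrs * 60)
    start_min <- floor(start_min)
    end_min <- pmin(start_min + round(hrs * 60), (day - 1) * .MIN_PER_DAY + 1320)
    ok <- end_min > start_min
    tibble::tibble(
      infant_id = infant_id[idx[ok]],
      parent_role = role,
      start = minutes_to_time(start_min[ok]),
      end = minutes_to_time(end_min[ok]),
      modality = sample(c("present", "holding", "skin_to_skin"),
        sum(ok),
        replace = TRUE, prob = c(0.6, 0.25, 0.15)
      )
    )
  })
  diary <- dplyr::arrange(
    dplyr::bind_rows(diary),
    .data$infant_id, .data$parent_role, .data$start
  )

  # recording-day audio segments (16-h recording, 06:00-22:00)
  segs <- simulate_segments(cfg, infants, diary, wf)

  # eye-tracking trials
  trials <- simulate_trials(cfg, infants, trait, attention)

  out <- list(
    infants = infants,
    diary = diary,
    segments = segs,
    trials = trials,
    ground_truth = list(
      config = cfg,
      latent = tibble::tibble(
        infant_id = infant_id,
        exposure_score = z,
        trait = trait,
        general_attention = attention,
        word_frequency_mother = wf[, "mother"],
        word_frequency_father = wf[, "father"],
        mother_absent_recording_day = absent_rec[, "mother"],
        father_absent_recording_day = absent_rec[, "father"] | single_parent
      )
    )
  )
  if (cfg$emit_gaze_streams) {
    out$gaze_streams <- streams_from_trials(out$trials, cfg)
  }
  structure(out, class = "synthetic_cohort")
}

simulate_segments <- function(cfg, infants, diary, wf) {
  n <- nrow(infants)
  rec_day <- cfg$recording_day
  seg_min <- cfg$segment_minutes
  day0 <- (rec_day - 1) * .MIN_PER_DAY
  seg_starts <- seq(360, 1320 - seg_min, by = seg_min) # 06:00-22:00 recording
  k <- length(seg_starts)

  dd <- diary
  dd$s <- as_minutes(dd$start)
  dd$e <- as_minutes(dd$end)
  dd <- dd[floor(dd$s / .MIN_PER_DAY) == rec_day - 1, , drop = FALSE]

  idx <- rep(seq_len(n), each = k)
  ss <- day0 + rep(seg_starts, n)
  se <- ss + seg_min

  ov_role <- function(role) {
    p <- dd[dd$parent_role == role, c("infant_id", "s", "e")]
    # at most one interval per infant per day by construction
    m <- match(infants$infant_id[idx], p$infant_id)
    ov <- pmax(0, pmin(se, p$e[m]) - pmax(ss, p$s[m]))
    ov[is.na(ov)] <- 0
    ov
  }
  ov_m <- ov_role("mother")
  ov_f <- ov_role("father")

  lam_f <- wf[idx, "mother"] * ov_m / 60 +
    cfg$background_words_per_hour[["female"]] * seg_min / 60
  lam_m <- wf[idx, "father"] * ov_f / 60 +
    cfg$background_words_per_hour[["male"]] * seg_min / 60

  tibble::tibble(
    infant_id = infants$infant_id[idx],
    start = minutes_to_time(ss),
    duration_s = seg_min * 60,
    female_words = rpois(length(idx), lam_f),
    male_words = rpois(length(idx), lam_m)
  )
}

simulate_trials <- function(cfg, infants, trait, attention = NULL) {
  if (is.null(attention)) {
    attention <- rep(0, nrow(infants))
  }
  n <- nrow(infants)
  scheds <- lapply(seq_len(n), function(i) {
    s <- generate_trial_schedule()
    s$infant_id <- infants$infant_id[i]
    s
  })
  tr <- dplyr::bind_rows(scheds)
  i <- match(tr$infant_id, infants$infant_id)
  nt <- nrow(tr)

  m <- cfg$trial_invalid_rate
  rate_i <- if (m <= 0) {
    rep(0, n)
  } else if (m >= 1) {
    rep(1, n)
  } else {
    rbeta(n, cfg$trial_invalid_kappa * m, cfg$trial_invalid_kappa * (1 - m))
  }
  invalid <- runif(nt) < rate_i[i]
  reason <- sample(
    c("insufficient_fixation", "invalid_data", "premature_shift", "wrong_direction"),
    nt,
    replace = TRUE, prob = c(0.4, 0.3, 0.15, 0.15)
  )

  is_face <- tr$stimulus_class == "face"
  p_nodis <- plogis(ifelse(
    is_face,
    qlogis(cfg$base_no_disengage[["face"]]) + cfg$trait_effect * trait[i],
    qlogis(cfg$base_no_disengage[["nonface"]])
  ) + attention[i])
  nodis <- runif(nt) < p_nodis
  lat <- rtrunc_lnorm(nt, cfg$latency_meanlog, cfg$latency_sdlog, 151, 1000)

  tr$central_fixation_prop <- round(runif(nt, 0.80, 1.0), 3)
  tr$shift_latency_ms <- ifelse(nodis, NA_real_, round(lat))
  tr$shift_direction <- ifelse(nodis, "none", "toward_distractor")
  tr$data_valid <- TRUE
  tr$disengaged <- !nodis

  # overwrite the invalid trials with their failure mode
  ins <- invalid & reason == "insufficient_fixation"
  tr$central_fixation_prop[ins] <- round(runif(sum(ins), 0.30, 0.74), 3)
  nov <- invalid & reason == "invalid_data"
  tr$data_valid[nov] <- FALSE
  pre <- invalid & reason == "premature_shift"
  tr$shift_latency_ms[pre] <- round(runif(sum(pre), 30, 150))
  tr$shift_direction[pre] <- "toward_distractor"
  tr$disengaged[pre] <- FALSE
  wd <- invalid & reason == "wrong_direction"
  tr$shift_latency_ms[wd] <- round(runif(sum(wd), 151, 1000))
  tr$shift_direction[wd] <- "away"
  tr$disengaged[wd] <- FALSE

  tr[, c(
    "infant_id", "block", "trial_index", "stimulus_class", "identity",
    "expression", "distractor_side", "central_fixation_prop",
    "shift_latency_ms", "shift_direction", "data_valid", "disengaged"
  )]
}

# log-normal truncated to (lo, hi) by inverse-CDF sampling
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  u <- runif(n, plnorm(lo, meanlog, sdlog), plnorm(hi, meanlog, sdlog))
  qlnorm(u, meanlog, sdlog)
}

#' Simulate a raw gaze-sample stream for one trial
#'
#' Emits `(time_ms, x_deg, y_deg)` samples at the configured rate from
#' central-stimulus onset (time 0) through distractor offset. Gaze rests on
#' the central stimulus; when `disengage` is `TRUE` it jumps to the
#' distractor location (12 degrees laterally on the cued side) at
#' `soa_ms + latency_ms`. Gaussian positional noise is added to every sample.
#' On a noise-free stream, [code_trial()] reproduces the injected outcome and
#' latency to within one sample period.
#'
#' @param trial One schedule row (list or one-row data frame) with at least
#'   `distractor_side`.
#' @param disengage Logical; does the gaze shift to the distractor?
#' @param latency_ms Shift latency after distractor onset, in
#'   `(0, distractor_duration_ms)`; ignored when `disengage` is `FALSE`.
#' @param noise_sd Positional noise SD in degrees.
#' @param sample_rate Sampling rate in Hz.
#' @param soa_ms,distractor_duration_ms Paradigm timing constants.
#' @return Tibble with `time_ms`, `x_deg`, `y_deg`.
#' @export
simulate_gaze_stream <- function(trial, disengage, latency_ms = NA,
                                 noise_sd = 0, sample_rate = 30,
                                 soa_ms = 1000, distractor_duration_ms = 2000) {
  if (disengage) {
    stopifnot(latency_ms > 0, latency_ms < distractor_duration_ms)
  }
  period <- 1000 / sample_rate
  time_ms <- seq(0, soa_ms + distractor_duration_ms, by = period)
  x <- rep(0, length(time_ms))
  y <- rep(0, length(time_ms))
  if (disengage) {
    side_sign <- if (trial$distractor_side == "left") -1 else 1
    moved <- time_ms >= soa_ms + latency_ms
    x[moved] <- side_sign * 12
  }
  tibble::tibble(
    time_ms = time_ms,
    x_deg = x + rnorm(length(time_ms), 0, noise_sd),
    y_deg = y + rnorm(length(time_ms), 0, noise_sd)
  )
}

# build streams for every trial of a simulated cohort
streams_from_trials <- function(trials, cfg) {
  res <- lapply(seq_len(nrow(trials)), function(j) {
    tr <- trials[j, ]
    dis <- isTRUE(tr$disengaged)
    st <- simulate_gaze_stream(
      tr,
      disengage = dis,
      latency_ms = if (dis) tr$shift_latency_ms else NA,
      noise_sd = cfg$gaze_noise_sd,
      sample_rate = cfg$sample_rate
    )
    st$infant_id <- tr$infant_id
    st$trial_index <- tr$trial_index
    st
  })
  dplyr::bind_rows(res)[, c("infant_id", "trial_index", "time_ms", "x_deg", "y_deg")]
}
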