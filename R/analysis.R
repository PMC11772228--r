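#' Full statistical analysis of a scored cohort
#'
#' Reproduces the study's statistical layer on an exposure table, condition
#' scores, and infant covariates: (1) the paired Wilcoxon test of face vs
#' non-face no-disengagement with the z/sqrt(N) effect size; (2) partial
#' Spearman correlations between per-site z-scored speech exposure (total,
#' mother, father) and face-condition no-disengagement, adjusted for the
#' non-face condition; (3) the same association additionally adjusted for
#' gestational age, maternal education, delivery type, sex, and birth
#' weight; (4) the parent-face analysis (parent-face score adjusted for the
#' unfamiliar-face score); (5) the exhaustive twin-subset sensitivity
#' analysis of the main correlation; and (6) site-level descriptives of word
#' frequency, presence, and exposure.
#'
#' Only infants flagged `included` by [condition_scores()] enter the
#' analysis. Variables are z-scored separately per site before the
#' correlation analyses. Twin pairs with only one included member are
#' treated as singletons in the sensitivity analysis. No multiple-testing
#' correction is applied.
#'
#' @param exposure Output of [exposure_table()].
#' @param scores Output of [condition_scores()].
#' @param infants Infant table.
#' @param covariates Covariate column names in `infants` for the adjusted
#'   analysis.
#' @param n_boot Bootstrap resamples for confidence intervals.
#' @param ci Compute bootstrap confidence intervals (slower)?
#' @param seed Seed for the bootstrap resampling.
#' @param max_sensitivity_pairs Upper bound on twin pairs for the exhaustive
#'   subset enumeration (2^k subsets); above it the sensitivity analysis is
#'   skipped (`NULL`) since exhaustive enumeration is only meaningful for the
#'   small family clusters it was designed for.
#' @return A list of class `facepref_analysis`.
#' @export
analyze_cohort <- function(exposure, scores, infants,
                           covariates = c(
                             "gestational_age_weeks", "maternal_education",
                             "delivery", "sex", "birth_weight_g"
                           ),
                           n_boot = 2000, ci = TRUE, seed = 1L,
                           max_sensitivity_pairs = 12L) {
  ex_w <- tidyr::pivot_wider(
    exposure[, c("infant_id", "parent_role", "exposure_words")],
    names_from = "parent_role", values_from = "exposure_words",
    names_prefix = "exposure_"
  )
  d <- dplyr::inner_join(
    scores[scores$included, , drop = FALSE], ex_w,
    by = "infant_id"
  )
  d <- dplyr::inner_join(d, infants, by = "infant_id")
  if (nrow(d) == 0) {
    stop("no included infants", call. = FALSE)
  }

  zs <- function(v) zscore_by_site(v, d$site)
  d$z_exposure_total <- zs(d$exposure_total)
  d$z_exposure_mother <- zs(d$exposure_mother)
  d$z_exposure_father <- zs(d$exposure_father)
  d$z_p_face <- zs(d$p_face)
  d$z_p_nonface <- zs(d$p_nonface)
  d$z_p_parent_face <- zs(d$p_parent_face)
  d$z_p_unfamiliar_face <- zs(d$p_unfamiliar_face)

  res <- list()
  res$face_vs_nonface <- wilcoxon_paired(d$p_face, d$p_nonface)
  res$face_vs_nonface$mean_face <- mean(d$p_face)
  res$face_vs_nonface$sd_face <- sd(d$p_face)
  res$face_vs_nonface$mean_nonface <- mean(d$p_nonface)
  res$face_vs_nonface$sd_nonface <- sd(d$p_nonface)
  res$parent_vs_unfamiliar_face <- wilcoxon_paired(
    d$p_parent_face, d$p_unfamiliar_face
  )

  res$exposure_total_face_pref <- adjusted_association(
    d$z_exposure_total, d$z_p_face, d$z_p_nonface,
    ci = ci, n_boot = n_boot, seed = seed
  )
  res$exposure_mother_face_pref <- adjusted_association(
    d$z_exposure_mother, d$z_p_face, d$z_p_nonface,
    ci = ci, n_boot = n_boot, seed = seed + 1L
  )
  res$exposure_father_face_pref <- adjusted_association(
    d$z_exposure_father, d$z_p_face, d$z_p_nonface,
    ci = ci, n_boot = n_boot, seed = seed + 2L
  )
  res$exposure_total_face_pref_adjusted <- adjusted_association(
    d$z_exposure_total, d$z_p_face, d$z_p_nonface,
    covariates = d[, covariates, drop = FALSE],
    ci = ci, n_boot = n_boot, seed = seed + 3L
  )
  res$exposure_parent_face_pref <- parent_face_association(
    d$z_exposure_total, d$z_p_parent_face, d$z_p_unfamiliar_face,
    ci = ci, n_boot = n_boot, seed = seed + 4L
  )

  # pairs with a single included member count as singletons here
  pair_ids <- d$twin_pair_id
  pair_n <- table(pair_ids[!is.na(pair_ids)])
  pair_ids[pair_ids %in% names(pair_n)[pair_n != 2]] <- NA
  k <- length(unique(pair_ids[!is.na(pair_ids)]))
  res$twin_sensitivity <- if (k <= max_sensitivity_pairs) {
    twin_subset_sensitivity(
      d, pair_ids,
      function(dd) {
        spearman_partial(dd$z_exposure_total, dd$z_p_face,
          data.frame(nonface = dd$z_p_nonface),
          ci = FALSE
        )$estimate
      }
    )
  } else {
    NULL
  }

  res$descriptives <- cohort_descriptives(exposure, infants, d)
  res$n_included <- nrow(d)
  res$data <- d
  structure(res, class = "facepref_analysis")
}

cohort_descriptives <- function(exposure, infants, included_data) {
  ex <- dplyr::inner_join(
    exposure, infants[, c("infant_id", "site")],
    by = "infant_id"
  )
  roles <- ex[ex$parent_role %in% c("mother", "father"), , drop = FALSE]
  med <- dplyr::summarise(
    dplyr::group_by(roles, .data$site, .data$parent_role),
    median_word_frequency = stats::median(.data$word_frequency[
      .data$frequency_source == "observed"
    ]),
    median_presence_hours_14d = stats::median(.data$presence_hours_14d),
    median_exposure_words = stats::median(.data$exposure_words),
    n_imputed = sum(.data$frequency_source != "observed"),
    .groups = "drop"
  )
  scores_by_site <- dplyr::summarise(
    dplyr::group_by(included_data, .data$site),
    n = dplyr::n(),
    mean_p_face = mean(.data$p_face),
    sd_p_face = sd(.data$p_face),
    mean_p_nonface = mean(.data$p_nonface),
    sd_p_nonface = sd(.data$p_nonface),
    .groups = "drop"
  )
  list(exposure_by_site = med, scores_by_site = scores_by_site)
}

#' @export
print.facepref_analysis <- function(x, ...) {
  cat("Speech exposure / face preference analysis (n included =", x$n_included, ")\n\n")
  cat(sprintf(
    "Face vs non-face no-disengagement: M = %.2f (SD %.2f) vs %.2f (SD %.2f)\n",
    x$face_vs_nonface$mean_face, x$face_vs_nonface$sd_face,
    x$face_vs_nonface$mean_nonface, x$face_vs_nonface$sd_nonface
  ))
  cat(sprintf(
    "  z = %.2f, p = %.3g, effect size z/sqrt(N) = %.2f\n\n",
    x$face_vs_nonface$z, x$face_vs_nonface$p_value, x$face_vs_nonface$estimate
  ))
  for (nm in c(
    "exposure_total_face_pref", "exposure_mother_face_pref",
    "exposure_father_face_pref", "exposure_total_face_pref_adjusted",
    "exposure_parent_face_pref"
  )) {
    cat(nm, ": ", sep = "")
    print(x[[nm]])
  }
  if (!is.null(x$twin_sensitivity)) {
    cat("\n")
    print(x$twin_sensitivity)
  }
  invisible(x)
}

#' Render an analysis as a markdown report
#'
#' @param results A `facepref_analysis`.
#' @return A character vector of markdown lines.
#' @export
report_markdown <- function(results) {
  r <- results
  fmt_ar <- function(a) {
    ci <- if (!is.na(a$ci_low)) sprintf(" [%.2f, %.2f]", a$ci_low, a$ci_high) else ""
    sprintf("r_s = %.2f%s, p = %.3g, n = %d", a$estimate, ci, a$p_value, a$n)
  }
  med <- r$descriptives$exposure_by_site
  lines <- c(
    "# Speech exposure and face preference: analysis report",
    "",
    sprintf("Included infants: %d", r$n_included),
    "",
    "## Exposure descriptives by site",
    "",
    "| site | role | median words/h (observed) | median presence h/14d | median exposure (words) | imputed |",
    "|---|---|---|---|---|---|",
    sprintf(
      "| %s | %s | %.0f | %.1f | %.0f | %d |",
      med$site, med$parent_role, med$median_word_frequency,
      med$median_presence_hours_14d, med$median_exposure_words, med$n_imputed
    ),
    "",
    "## Face preference",
    "",
    sprintf(
      "No-disengagement probability, face M = %.2f (SD %.2f) vs non-face M = %.2f (SD %.2f); z = %.2f, p = %.3g, effect size = %.2f.",
      r$face_vs_nonface$mean_face, r$face_vs_nonface$sd_face,
      r$face_vs_nonface$mean_nonface, r$face_vs_nonface$sd_nonface,
      r$face_vs_nonface$z, r$face_vs_nonface$p_value, r$face_vs_nonface$estimate
    ),
    "",
    "## Exposure--face-preference correlations (per-site z-scored)",
    "",
    sprintf("- Total exposure: %s", fmt_ar(r$exposure_total_face_pref)),
    sprintf("- Mother's speech: %s", fmt_ar(r$exposure_mother_face_pref)),
    sprintf("- Father's speech: %s", fmt_ar(r$exposure_father_face_pref)),
    sprintf(
      "- Covariate-adjusted total: %s",
      fmt_ar(r$exposure_total_face_pref_adjusted)
    ),
    sprintf("- Parent-face preference: %s", fmt_ar(r$exposure_parent_face_pref)),
    "",
    "## Twin-subset sensitivity",
    "",
    if (is.null(r$twin_sensitivity)) {
      "Not computed (too many twin pairs for exhaustive enumeration)."
    } else {
      sprintf(
        "%d subsets; r_s range %.2f--%.2f, median %.2f.",
        r$twin_sensitivity$n_subsets, r$twin_sensitivity$min,
        r$twin_sensitivity$max, r$twin_sensitivity$median
      )
    }
  )
  lines
}
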