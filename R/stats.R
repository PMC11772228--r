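#' Standardize values within each site
#'
#' Transforms a variable into z-scores separately for each study site, so
#' that site-level differences (e.g. in word counts or disengagement
#' probability) do not drive pooled correlations. Within each site the
#' result has mean 0 and sample SD 1.
#'
#' @param values Numeric vector.
#' @param site_labels Site label per element.
#' @return Numeric vector of within-site z-scores.
#' @examples
#' zscore_by_site(c(1, 2, 3), rep("A", 3))
#' @export
zscore_by_site <- function(values, site_labels) {
  stopifnot(length(values) == length(site_labels))
  for (s in unique(site_labels)) {
    v <- values[site_labels == s]
    if (length(unique(v[!is.na(v)])) < 2) {
      stop("values are constant within site ", s, "; cannot z-score",
        call. = FALSE
      )
    }
  }
  mu <- stats::ave(values, site_labels, FUN = function(x) mean(x, na.rm = TRUE))
  sdv <- stats::ave(values, site_labels, FUN = function(x) sd(x, na.rm = TRUE))
  (values - mu) / sdv
}

#' Paired Wilcoxon signed-rank test with z/sqrt(N) effect size
#'
#' Tests paired differences `x - y` with the Wilcoxon signed-rank statistic.
#' Zero differences are dropped (classical treatment) and tied absolute
#' differences receive average ranks. The standardized statistic `z` comes
#' from the normal approximation with tie correction, and the effect size is
#' `|z| / sqrt(N)` with `N` the number of retained pairs. The p-value is
#' exact (signed-rank distribution) when there are no ties or zeros and
#' `N <= 50`, otherwise from the normal approximation.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @return An `analysis_result` list: `estimate` (the effect size), `z`,
#'   `statistic` (V, sum of positive ranks), `p_value`, `n` (retained
#'   pairs), `method`.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all paired differences are zero; the test is undefined", call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - mu) / sqrt(sigma2)
  exact <- n <= 50 && !any(duplicated(abs(d)))
  p <- if (exact) {
    min(1, 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n)))
  } else {
    2 * pnorm(-abs(z))
  }
  analysis_result(
    statistic_name = "wilcoxon_signed_rank",
    estimate = abs(z) / sqrt(n),
    statistic = v,
    z = z,
    p_value = p,
    n = n,
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all variables (average ranks for ties), residualizes the
#' ranked `x` and `y` on the ranked covariates by least squares, and
#' correlates the residuals (rank-then-residualize partial correlation). With
#' no covariates this reduces exactly to the ordinary Spearman correlation.
#' The p-value uses the t approximation with `n - 2 - k` degrees of freedom
#' (`k` covariates); the confidence interval, when requested, is a seeded
#' bootstrap percentile interval over case resamples.
#'
#' When a residualized variable is (numerically) constant -- e.g. `y`
#' adjusted for itself -- the estimate is undefined; the result is flagged
#' `degenerate` with a warning.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame (or vector) of covariates; ranked
#'   column-wise before residualization. `NULL` for a plain Spearman
#'   correlation.
#' @param ci Compute a bootstrap percentile confidence interval?
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap (local RNG).
#' @param statistic_name Label stored in the result.
#' @return An `analysis_result` list with `estimate` (r_s), `ci_low`,
#'   `ci_high`, `p_value`, `n`, `adjustment_set`, `degenerate`.
#' @export
spearman_partial <- function(x, y, covariates = NULL, ci = FALSE,
                             n_boot = 2000, conf_level = 0.95, seed = NULL,
                             statistic_name = "spearman_partial") {
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
  }
  cc <- if (is.null(covariates)) {
    complete.cases(x, y)
  } else {
    complete.cases(x, y, covariates)
  }
  x <- x[cc]
  y <- y[cc]
  z <- if (is.null(covariates)) NULL else covariates[cc, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(z)) 0L else ncol(z)
  if (n <= k + 2) {
    stop("need n > number of covariates + 2", call. = FALSE)
  }

  est <- rank_partial_cor(x, y, z)
  if (is.na(est$r)) {
    warning("degenerate partial correlation (constant residuals)", call. = FALSE)
    return(analysis_result(
      statistic_name = statistic_name, estimate = NA_real_,
      p_value = NA_real_, n = n,
      adjustment_set = names(z), degenerate = TRUE
    ))
  }
  df <- n - 2 - k
  r <- est$r
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r) * sqrt(df / (1 - r^2)), df)

  ci_low <- ci_high <- NA_real_
  if (ci) {
    boot_fun <- function() {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        rank_partial_cor(x[idx], y[idx], if (is.null(z)) NULL else z[idx, , drop = FALSE])$r
      }, numeric(1))
    }
    rb <- if (is.null(seed)) boot_fun() else withr::with_seed(seed, boot_fun())
    qs <- quantile(rb, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
      na.rm = TRUE, names = FALSE
    )
    ci_low <- qs[1]
    ci_high <- qs[2]
  }
  analysis_result(
    statistic_name = statistic_name, estimate = r,
    ci_low = ci_low, ci_high = ci_high, p_value = p, n = n,
    adjustment_set = names(z), degenerate = FALSE
  )
}

# Pearson correlation of rank residuals; r = NA when residuals are constant.
rank_partial_cor <- function(x, y, z) {
  rx <- rank(x)
  ry <- rank(y)
  if (length(unique(rx)) < 2 || length(unique(ry)) < 2) {
    stop("x or y is constant after ranking; correlation undefined", call. = FALSE)
  }
  if (!is.null(z) && ncol(z) > 0) {
    zr <- vapply(z, function(col) rank(encode_covariate(col)), numeric(nrow(z)))
    qz <- cbind(1, zr)
    rx <- stats::lm.fit(qz, rx)$residuals
    ry <- stats::lm.fit(qz, ry)$residuals
  } else {
    rx <- rx - mean(rx)
    ry <- ry - mean(ry)
  }
  sx <- sqrt(sum(rx^2))
  sy <- sqrt(sum(ry^2))
  if (sx < 1e-8 || sy < 1e-8) {
    return(list(r = NA_real_))
  }
  list(r = sum(rx * ry) / (sx * sy))
}

# ordinal/binary covariates enter as integer codes before ranking
encode_covariate <- function(col) {
  if (is.numeric(col)) {
    col
  } else if (is.logical(col)) {
    as.integer(col)
  } else if (is.factor(col)) {
    as.integer(col)
  } else {
    as.integer(factor(col))
  }
}

#' Exposure--face-preference association with covariate adjustment
#'
#' The study's hypothesis test: partial Spearman correlation between speech
#' exposure and the no-disengagement probability in the face condition,
#' always adjusted for the non-face no-disengagement probability, and
#' optionally for clinical/demographic covariates (gestational age, parental
#' education, delivery type, sex, birth weight). Inputs are expected to be
#' z-scored per site beforehand (see [zscore_by_site()]). Categorical
#' covariates are coded as integers before ranking; rows with missing
#' covariates are dropped listwise (the reported `n` reflects this).
#'
#' @param exposure,face_score,nonface_score Aligned numeric vectors.
#' @param covariates Optional data frame of additional covariates.
#' @param ... Passed on to [spearman_partial()] (`ci`, `n_boot`, `seed`, ...).
#' @return An `analysis_result`.
#' @export
adjusted_association <- function(exposure, face_score, nonface_score,
                                 covariates = NULL, ...) {
  adj <- data.frame(nonface_score = nonface_score)
  if (!is.null(covariates)) {
    adj <- cbind(adj, as.data.frame(covariates))
  }
  spearman_partial(exposure, face_score, adj,
    statistic_name = "adjusted_association", ...
  )
}

#' Parent-face preference association
#'
#' Partial Spearman correlation between speech exposure and the
#' no-disengagement probability for the parent's face, adjusted for the
#' probability for unfamiliar faces. A constant unfamiliar-face covariate is
#' dropped with a warning, reducing to a plain Spearman correlation.
#'
#' @param exposure,parent_face_score,unfamiliar_face_score Aligned numeric
#'   vectors (per-site z-scored).
#' @param ... Passed on to [spearman_partial()].
#' @return An `analysis_result`.
#' @export
parent_face_association <- function(exposure, parent_face_score,
                                    unfamiliar_face_score, ...) {
  cc <- complete.cases(exposure, parent_face_score, unfamiliar_face_score)
  if (length(unique(unfamiliar_face_score[cc])) < 2) {
    warning("unfamiliar-face score is constant; covariate dropped", call. = FALSE)
    return(spearman_partial(exposure, parent_face_score,
      statistic_name = "parent_face_association", ...
    ))
  }
  spearman_partial(exposure, parent_face_score,
    data.frame(unfamiliar_face_score = unfamiliar_face_score),
    statistic_name = "parent_face_association", ...
  )
}

#' Exhaustive twin-subset sensitivity analysis
#'
#' With `k` twin pairs in the sample, re-runs an analysis on all `2^k`
#' subsets that keep every singleton and exactly one member of each pair,
#' assessing whether a result is robust to family clustering (with 7 pairs:
#' 128 subsets).
#'
#' @param data Data frame, one row per infant.
#' @param twin_pair_ids Pair identifier per row; `NA` for singletons. Every
#'   non-missing pair id must occur exactly twice.
#' @param analysis Callable `function(data_subset) -> numeric` returning the
#'   statistic of interest (e.g. a partial Spearman estimate).
#' @return A list of class `subset_sensitivity`: `n_subsets`, `values`,
#'   `min`, `max`, `median`, and `subsets` (row indices of each subset).
#' @export
twin_subset_sensitivity <- function(data, twin_pair_ids, analysis) {
  stopifnot(nrow(data) == length(twin_pair_ids))
  tab <- table(twin_pair_ids[!is.na(twin_pair_ids)])
  if (any(tab != 2)) {
    stop(
      "each twin pair id must occur exactly twice; offending pair(s): ",
      paste(names(tab)[tab != 2], collapse = ", "),
      call. = FALSE
    )
  }
  pair_ids <- names(tab)
  k <- length(pair_ids)
  if (k > 20) {
    stop("refusing to enumerate more than 2^20 subsets", call. = FALSE)
  }
  singles <- which(is.na(twin_pair_ids))
  members <- lapply(pair_ids, function(p) which(twin_pair_ids == p))

  choices <- if (k == 0) {
    matrix(integer(0), nrow = 1, ncol = 0)
  } else {
    as.matrix(expand.grid(rep(list(1:2), k)))
  }
  subsets <- lapply(seq_len(nrow(choices)), function(i) {
    sort(c(singles, vapply(seq_len(k), function(j) {
      members[[j]][choices[i, j]]
    }, integer(1))))
  })
  values <- vapply(subsets, function(rows) {
    analysis(data[rows, , drop = FALSE])
  }, numeric(1))
  structure(
    list(
      n_subsets = length(subsets),
      values = values,
      min = min(values),
      max = max(values),
      median = stats::median(values),
      subsets = subsets
    ),
    class = "subset_sensitivity"
  )
}

#' @export
print.subset_sensitivity <- function(x, ...) {
  cat(
    "Twin-subset sensitivity analysis:", x$n_subsets, "subsets\n",
    sprintf(
      " r ranged from %.3f to %.3f, median %.3f\n",
      x$min, x$max, x$median
    )
  )
  invisible(x)
}

# light-weight container for a statistic with inference
analysis_result <- function(statistic_name, estimate, ci_low = NA_real_,
                            ci_high = NA_real_, p_value = NA_real_, n = NA_integer_,
                            adjustment_set = NULL, ...) {
  structure(
    list(
      statistic_name = statistic_name,
      estimate = estimate,
      ci_low = ci_low,
      ci_high = ci_high,
      p_value = p_value,
      n = n,
      adjustment_set = adjustment_set,
      ...
    ),
    class = "analysis_result"
  )
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(x$statistic_name, ": estimate = ", sprintf("%.3f", x$estimate), sep = "")
  if (!is.na(x$ci_low)) {
    cat(sprintf(" [%.2f, %.2f]", x$ci_low, x$ci_high))
  }
  cat(sprintf(", p = %.4g, n = %d\n", x$p_value, x$n))
  if (!is.null(x$adjustment_set)) {
    cat("  adjusted for:", paste(x$adjustment_set, collapse = ", "), "\n")
  }
  invisible(x)
}
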