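# rank-based statistics layer

test_that("zscore_by_site standardizes within each site", {
  expect_equal(zscore_by_site(c(1, 2, 3), rep("A", 3)), c(-1, 0, 1))
  withr::with_seed(30, {
    x <- rnorm(40, mean = c(rep(5, 20), rep(-3, 20)))
    site <- rep(c("A", "B"), each = 20)
    z <- zscore_by_site(x, site)
    for (s in c("A", "B")) {
      expect_equal(mean(z[site == s]), 0, tolerance = 1e-12)
      expect_equal(sd(z[site == s]), 1, tolerance = 1e-12)
      expect_equal(
        z[site == s],
        (x[site == s] - mean(x[site == s])) / sd(x[site == s])
      )
    }
  })
  expect_error(zscore_by_site(c(1, 1, 1), rep("A", 3)), "constant")
})

test_that("an all-positive shift gives the maximal effect size and small p", {
  x <- seq(1, 2, length.out = 12)
  y <- x - seq(0.4, 0.6, length.out = 12) # distinct, all-positive differences
  res <- wilcoxon_paired(x, y)
  expect_lt(res$p_value, 0.01)
  n <- 12
  z_max <- (n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  expect_equal(res$estimate, z_max / sqrt(n), tolerance = 1e-12)
  expect_error(wilcoxon_paired(x, x), "undefined")
})

test_that("small-sample p equals exact sign-flip enumeration and wilcox.test", {
  withr::with_seed(31, {
    for (n in c(6, 8, 10)) {
      for (rep in 1:3) {
        x <- round(rnorm(n), 2)
        y <- round(rnorm(n), 2)
        d <- x - y
        # regenerate on the rare tie/zero draw to stay on the exact path
        while (any(d == 0) || any(duplicated(abs(d[d != 0])))) {
          y <- round(rnorm(n), 2)
          d <- x - y
        }
        res <- wilcoxon_paired(x, y)
        expect_equal(res$p_value, oracle_wilcoxon_enum_p(d), tolerance = 1e-12)
        ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = TRUE))
        expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
      }
    }
  })
})

test_that("ties and zeros fall back to the corrected normal approximation", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(1, 1, 1, 2, 7, 2, 9, 4) # one zero difference, tied magnitudes
  res <- wilcoxon_paired(x, y)
  expect_equal(res$n, 7) # zero difference dropped
  expect_equal(res$method, "normal approximation")
  d <- (x - y)[x - y != 0]
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  ties <- table(r)
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
  z <- (v - n * (n + 1) / 4) / sig
  expect_equal(res$z, z)
  expect_equal(res$p_value, 2 * pnorm(-abs(z)))
})

test_that("the wilcoxon test is calibrated under the null", {
  withr::with_seed(32, {
    rej <- replicate(1000, {
      x <- rnorm(20)
      y <- rnorm(20)
      wilcoxon_paired(x, y)$p_value < 0.05
    })
    expect_gte(mean(rej), 0.03)
    expect_lte(mean(rej), 0.07)
  })
})

test_that("spearman_partial with no covariates is textbook Spearman", {
  withr::with_seed(33, {
    x <- rnorm(25)
    expect_equal(spearman_partial(x, exp(x))$estimate, 1.0)
    for (rep in 1:5) {
      x <- rnorm(30)
      y <- rnorm(30) + 0.5 * x
      res <- spearman_partial(x, y)
      expect_equal(res$estimate, cor(x, y, method = "spearman"),
        tolerance = 1e-12
      )
    }
    # with ties
    x <- sample(1:5, 40, replace = TRUE)
    y <- sample(1:4, 40, replace = TRUE)
    expect_equal(
      spearman_partial(x, y)$estimate,
      cor(x, y, method = "spearman"),
      tolerance = 1e-12
    )
  })
})

test_that("spearman_partial is invariant under strictly monotone transforms", {
  withr::with_seed(34, {
    x <- rnorm(40)
    y <- rnorm(40) + 0.4 * x
    z <- data.frame(c1 = rnorm(40), c2 = sample(0:1, 40, replace = TRUE))
    a <- spearman_partial(x, y, z)
    b <- spearman_partial(exp(x), y^3 + 5 * y, z)
    expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  })
})

test_that("adjusting y for itself is flagged degenerate", {
  withr::with_seed(35, {
    x <- rnorm(20)
    y <- rnorm(20)
    expect_warning(
      res <- spearman_partial(x, y, data.frame(y = y)),
      "degenerate"
    )
    expect_true(res$degenerate)
    expect_true(is.na(res$estimate))
  })
  expect_error(spearman_partial(rep(1, 10), rnorm(10)), "constant")
})

test_that("bootstrap confidence intervals are seeded and bracket the estimate", {
  withr::with_seed(36, {
    x <- rnorm(50)
    y <- 0.6 * x + rnorm(50)
    a <- spearman_partial(x, y, ci = TRUE, n_boot = 500, seed = 7)
    b <- spearman_partial(x, y, ci = TRUE, n_boot = 500, seed = 7)
    expect_identical(a$ci_low, b$ci_low)
    expect_lte(a$ci_low, a$estimate)
    expect_gte(a$ci_high, a$estimate)
  })
})

test_that("independent covariates leave the association essentially unchanged", {
  withr::with_seed(37, {
    n <- 80
    x <- rnorm(n)
    nonface <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    cov <- data.frame(
      ga = rnorm(n), edu = sample(1:4, n, TRUE),
      sex = sample(c("male", "female"), n, TRUE)
    )
    un <- adjusted_association(x, y, nonface, ci = TRUE, n_boot = 500, seed = 1)
    ad <- adjusted_association(x, y, nonface,
      covariates = cov,
      ci = FALSE
    )
    expect_gte(ad$estimate, un$ci_low)
    expect_lte(ad$estimate, un$ci_high)
    expect_equal(
      ad$adjustment_set,
      c("nonface_score", "ga", "edu", "sex")
    )
  })
  # face score adjusted for an identical nonface score is degenerate
  withr::with_seed(38, {
    y <- rnorm(20)
    expect_warning(
      res <- adjusted_association(rnorm(20), y, y),
      "degenerate"
    )
    expect_true(res$degenerate)
  })
})

test_that("parent_face_association drops a constant covariate with a warning", {
  withr::with_seed(39, {
    x <- rnorm(30)
    y <- 0.5 * x + rnorm(30)
    expect_warning(
      res <- parent_face_association(x, y, rep(0.5, 30)),
      "constant"
    )
    expect_equal(res$estimate, cor(x, y, method = "spearman"), tolerance = 1e-12)
  })
})

test_that("twin subset enumeration matches manual enumeration", {
  # 2 pairs + 4 singletons -> 4 subsets of size 6
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6, 7, 8), y = c(2, 1, 4, 3, 6, 5, 8, 7))
  pairs <- c("P1", "P1", "P2", "P2", NA, NA, NA, NA)
  res <- twin_subset_sensitivity(d, pairs, function(dd) sum(dd$x))
  expect_equal(res$n_subsets, 4L)
  manual <- c(
    sum(d$x[c(1, 3, 5:8)]), sum(d$x[c(2, 3, 5:8)]),
    sum(d$x[c(1, 4, 5:8)]), sum(d$x[c(2, 4, 5:8)])
  )
  expect_equal(sort(res$values), sort(manual))
  expect_true(all(vapply(res$subsets, length, integer(1)) == 6L))
  # 0 pairs -> single subset = full sample
  res0 <- twin_subset_sensitivity(d, rep(NA, 8), function(dd) sum(dd$x))
  expect_equal(res0$n_subsets, 1L)
  expect_equal(res0$min, sum(d$x))
  expect_equal(res0$median, res0$max)
  # malformed pair
  expect_error(
    twin_subset_sensitivity(d, c("P1", NA, NA, NA, NA, NA, NA, NA), sum),
    "exactly twice"
  )
})

test_that("subset counts are 2^k for k pairs", {
  withr::with_seed(40, {
    for (k in 0:8) {
      n_single <- 5
      n <- n_single + 2 * k
      d <- tibble::tibble(x = rnorm(n))
      pairs <- c(rep(NA, n_single), rep(sprintf("P%d", seq_len(k)), each = 2))
      res <- twin_subset_sensitivity(d, pairs, function(dd) mean(dd$x))
      expect_equal(res$n_subsets, 2L^k)
      # every subset keeps all singletons and one member per pair
      for (s in res$subsets) {
        expect_true(all(seq_len(n_single) %in% s))
        expect_equal(length(s), n_single + k)
      }
    }
  })
})
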