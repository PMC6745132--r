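test_that("thresholding keeps exactly the stated survivors and is idempotent", {
  tb <- estimate_table(
    subject = "s1", group = "control", unit = 1:5, roi = "V1",
    condition = "AS", param = "prf_size",
    value = c(1, 2, 3, 4, 5),
    ecc = c(5, 5, 11, 3, 10.2),
    ve = c(0.10, 0.20, 0.25, 0.50, 0.30))
  kept <- apply_thresholds(tb)
  expect_identical(kept$unit, c(2L, 4L, 5L))   # ve >= .20 AND ecc <= 10.2
  expect_identical(apply_thresholds(kept), kept)
  expect_identical(apply_thresholds(tb, ve_min = 0, ecc_max = Inf), tb)
  expect_warning(apply_thresholds(tb, ve_min = 1.01), "no estimates")
  expect_identical(area_group_of(c("V1", "hV4", "foo")),
                   c("early", "late", NA_character_))
})

test_that("binned medians agree with a sort-based oracle", {
  b <- binned_median_size(c(0.2, 0.5, 0.9), c(1, 2, 3), 1, n_iter = 50L)
  expect_equal(b$median, 2)
  expect_equal(b$n, 3L)

  b2 <- binned_median_size(c(0.5, 1.5, 2.5), c(4, 5, 6), 1, n_iter = 50L)
  expect_equal(b2$median, c(4, 5, 6))

  set.seed(20)
  for (i in 1:5) {
    ecc <- runif(60, 0, 8)
    size <- rgamma(60, 2)
    b <- binned_median_size(ecc, size, 1, n_iter = 50L)
    for (r in seq_len(nrow(b))) {
      v <- sort(size[ecc >= b$bin_lo[r] & ecc < b$bin_hi[r]])
      med_or <- if (length(v) %% 2L) v[(length(v) + 1L) / 2L]
                else mean(v[length(v) / 2L + 0:1])
      expect_equal(b$median[r], med_or)
    }
    expect_true(all(b$bin_hi - b$bin_lo == 1))
  }
})

test_that("median bootstrap CIs behave and reach nominal coverage", {
  expect_equal(bootstrap_median_ci(rep(4, 10), 200L), c(4, 4))
  set.seed(3)
  x <- rnorm(40)
  ci <- bootstrap_median_ci(x, 1000L, seed = 5L)
  expect_lte(ci[1L], median(x))
  expect_gte(ci[2L], median(x))
  expect_identical(ci, bootstrap_median_ci(x, 1000L, seed = 5L))

  # coverage over 500 normal samples of n = 50 within +/- 4 points of 95%
  set.seed(99)
  hits <- vapply(1:500, function(i) {
    v <- rnorm(50)
    ci <- bootstrap_median_ci(v, 1000L, seed = i)
    ci[1L] <= 0 && 0 <= ci[2L]
  }, logical(1L))
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.99)
})

test_that("trend fits recover exact lines and printed slope differences", {
  ecc <- seq(0.5, 8.5, by = 1)
  b1 <- binned_median_size(ecc, 1 + 2 * ecc, 1, n_iter = 20L)
  f1 <- fit_size_ecc_trend(b1)
  expect_equal(f1$slope, 2)
  expect_equal(f1$intercept, 1)

  # two exact lines with the published early-visual-area slopes
  bA <- binned_median_size(ecc, 0.5 + 3.09 * ecc, 1, n_iter = 20L)
  bB <- binned_median_size(ecc, 0.5 - 11.43 * ecc, 1, n_iter = 20L)
  cmp <- compare_trends(bA, bB)
  expect_equal(cmp$delta_slope, 14.52)
  expect_equal(cmp$delta_slope,
               fit_size_ecc_trend(bA)$slope - fit_size_ecc_trend(bB)$slope)

  expect_error(fit_size_ecc_trend(b1[1:2, ]), ">= 3")

  # L1 mode recovers the same exact line
  f_l1 <- fit_size_ecc_trend(b1, method = "l1")
  expect_equal(f_l1$slope, 2, tolerance = 1e-4)
})

test_that("slope-difference F-test agrees with a permutation oracle", {
  set.seed(31)
  decisions <- vapply(1:40, function(i) {
    n <- 8L
    ecc <- seq(0.5, by = 1, length.out = n)
    slope_gap <- sample(c(0, 1.5), 1L)
    ya <- 1 + (1 + slope_gap) * ecc + rnorm(n, 0, 0.6)
    yb <- 1 + 1 * ecc + rnorm(n, 0, 0.6)
    ba <- tibble::tibble(bin_mid = ecc, median = ya)
    bb <- tibble::tibble(bin_mid = ecc, median = yb)
    f <- compare_trends(ba, bb)
    # Freedman-Lane permutation oracle: permute residuals of the
    # common-slope model and recompute the interaction F
    dat <- data.frame(y = c(ya, yb), ecc = c(ecc, ecc),
                      g = rep(c("a", "b"), each = n))
    fstat <- function(d) anova(lm(y ~ ecc + g, d), lm(y ~ ecc * g, d))$F[2L]
    f_obs <- fstat(dat)
    fit0 <- lm(y ~ ecc + g, dat)
    r0 <- resid(fit0); fh <- fitted(fit0)
    perm <- vapply(1:300, function(j) {
      d2 <- dat; d2$y <- fh + sample(r0); fstat(d2)
    }, numeric(1L))
    p_perm <- mean(perm >= f_obs)
    (f$p_value < 0.05) == (p_perm < 0.05)
  }, logical(1L))
  expect_gte(mean(decisions), 0.95)
})

test_that("relative frequency distributions are normalised histograms", {
  h <- relative_frequency(c(0.2, 0.7, 1.4), 0.5)
  expect_equal(h$freq, rep(1 / 3, 3))
  expect_equal(sum(h$freq), 1)

  set.seed(12)
  for (i in 1:5) {
    v <- rgamma(50, 2)
    h <- relative_frequency(v, 0.5)
    expect_equal(sum(h$freq), 1, tolerance = 1e-12)
    # counting oracle
    for (r in sample(nrow(h), 3L)) {
      expect_equal(h$freq[r],
                   mean(v >= h$bin_lo[r] & v < h$bin_hi[r]))
    }
  }

  hs <- replicate(4, relative_frequency(c(0.2, 0.7, 1.4), 0.5),
                  simplify = FALSE)
  gm <- group_mean_distribution(hs)
  expect_equal(gm$mean_freq, hs[[1L]]$freq)
  expect_equal(gm$ci_hi - gm$ci_lo, rep(0, 3))
  h_other <- relative_frequency(c(0.2, 2.6), 0.5)
  expect_error(group_mean_distribution(list(hs[[1L]], h_other)),
               "share bin edges")
})

test_that("case-versus-controls median tests match the closed-form t", {
  controls <- c(3, 4, 5, 4, 3, 4, 5, 3, 4, 4, 3, 4)
  res <- case_vs_controls_median_test(5, controls)
  d <- 5 - controls
  expect_equal(res$mean_diff, mean(d))
  expect_equal(res$t, bf_one_sample_t(d))
  expect_identical(res$df, 11)
  expect_equal(res$p_value, 2 * pt(-abs(res$t), 11))
  expect_false(res$degenerate)

  degen <- case_vs_controls_median_test(4, rep(4, 5))
  expect_true(degen$degenerate)
  expect_equal(degen$mean_diff, 0)
  expect_true(is.na(degen$t))
})

test_that("paired condition tests mask first and match the closed form", {
  a <- c(5, 6, 7, 8, 9)
  b <- a - 1 + c(0.1, -0.1, 0.2, -0.2, 0)
  mask <- rep(TRUE, 5)
  res <- paired_condition_test(a, b, mask)
  d <- a - b
  expect_equal(res$t, bf_one_sample_t(d))
  expect_equal(res$df, 4)

  # identical vectors: zero difference everywhere
  same <- paired_condition_test(a, a, mask)
  expect_equal(same$t, 0)
  expect_true(same$degenerate)

  # out-of-mask values can never change the result
  a2 <- a; b2 <- b
  a2[2L] <- 1e6; b2[2L] <- -1e6
  mask2 <- c(TRUE, FALSE, TRUE, TRUE, TRUE)
  expect_identical(paired_condition_test(a, b, mask2),
                   paired_condition_test(a2, b2, mask2))
})
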