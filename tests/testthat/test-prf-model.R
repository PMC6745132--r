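test_that("gaussian-aperture drive handles blank frames and the delta limit", {
  m <- tiny_movie()
  d <- gaussian_aperture_overlap(-3, 1, 1, m)
  expect_true(all(d >= 0))
  blank <- apply(m$frames, 3L, sum) == 0
  expect_true(all(d[blank] == 0))

  # tiny sigma centred exactly on a pixel inside the bar: drive ~ pixel area
  f1 <- which(!blank)[3L]
  on_pix <- which(m$frames[, , f1] == 1, arr.ind = TRUE)[10L, ]
  x0 <- m$grid_x[on_pix[2L]]; y0 <- m$grid_y[on_pix[1L]]
  d_tiny <- gaussian_aperture_overlap(x0, y0, 1e-3, m)[f1]
  expect_equal(d_tiny, m$pixel_area, tolerance = 1e-10)

  expect_error(gaussian_aperture_overlap(0, 0, 0, m), "positive")
})

test_that("drive integration agrees with a 10x subpixel oracle for sigma >= 0.25", {
  m <- tiny_movie(101L)
  frames <- c(3L, 6L, 40L, 70L, 100L)
  for (sigma in c(0.25, 0.5, 1, 2)) {
    for (ctr in list(c(-3, 1), c(-6, -2))) {
      d_pkg <- gaussian_aperture_overlap(ctr[1L], ctr[2L], sigma, m)
      d_or <- vapply(frames, function(t)
        subpixel_overlap(ctr[1L], ctr[2L], sigma, m$frames[, , t], m$grid_x),
        numeric(1L))
      expect_lt(max(abs(d_pkg[frames] - d_or)) / max(d_or), 0.01)
    }
  }
})

test_that("predictions are linear in amplitude and track scan truncation", {
  m <- tiny_movie()
  h <- tiny_hrf()
  p1 <- prf_prediction(list(x0 = -3, y0 = 0, sigma = 1), m, h)
  expect_length(p1, 128L)

  # blank-only movie gives a constant (zero-drive) prediction
  blank <- aperture_movie(array(0, dim = c(11, 11, 30)), 1.5, 10.21)
  expect_true(all(prf_prediction(list(x0 = 0, y0 = 0, sigma = 1),
                                 blank, h) == 0))

  # doubling beta doubles the mean-removed prediction
  p2 <- prf_prediction(list(x0 = -3, y0 = 0, sigma = 1, beta = 2,
                            baseline = 5), m, h)
  expect_equal(p2 - mean(p2), 2 * (p1 - mean(p1)))

  # a 126-frame truncated movie yields exactly 2 fewer samples
  p_short <- prf_prediction(list(x0 = -3, y0 = 0, sigma = 1),
                            truncate_for_short_scan(m, 2L), h)
  expect_length(p_short, 126L)
  st <- scan_timing(204, 1.5, 12)
  expect_silent(prf_prediction(list(x0 = -3, y0 = 0, sigma = 1), m, h, st))
  expect_error(prf_prediction(list(x0 = -3, y0 = 0, sigma = 1),
                              truncate_for_short_scan(m, 2L), h, st),
               "truncate")
})

test_that("on-meridian mirrored models degenerate to the unilateral model", {
  m <- tiny_movie()
  h <- tiny_hrf()
  uni <- prf_prediction(list(x0 = 0, y0 = 4, sigma = 1.5), m, h)
  mv <- bilateral_prediction(list(x0 = 0, y0 = 4, sigma = 1.5), "vertical",
                             m, h)
  expect_equal(mv, 2 * uni)   # proportional, hence identical VE
  set.seed(1)
  y <- uni + rnorm(length(uni), 0, 0.1 * sd(uni))
  expect_equal(variance_explained(y, mv)$ve, variance_explained(y, uni)$ve)

  uni_h <- prf_prediction(list(x0 = -4, y0 = 0, sigma = 1.5), m, h)
  mh <- bilateral_prediction(list(x0 = -4, y0 = 0, sigma = 1.5),
                             "horizontal", m, h)
  expect_equal(mh, 2 * uni_h)
})

test_that("on a one-hemifield movie the mirrored lobe adds nothing", {
  m <- mask_hemifield(tiny_movie(), "left")
  h <- tiny_hrf()
  p_uni <- prf_prediction(list(x0 = -6, y0 = 2, sigma = 0.8), m, h)
  p_mv <- bilateral_prediction(list(x0 = -6, y0 = 2, sigma = 0.8),
                               "vertical", m, h)
  expect_equal(p_mv, p_uni, tolerance = 1e-6)
  # and the mirrored parameterisation picks out the stimulated-hemifield lobe
  p_mv2 <- bilateral_prediction(list(x0 = 6, y0 = 2, sigma = 0.8),
                                "vertical", m, h)
  expect_equal(p_mv2, p_uni, tolerance = 1e-6)
})

test_that("variance explained matches closed-form least squares", {
  y <- c(1, 2, 4)
  p <- c(0, 1, 2)
  fit <- variance_explained(y, p)
  r2 <- cor(y, p)^2
  expect_equal(fit$ve, r2)
  b <- cov(y, p) / var(p)
  expect_equal(fit$beta, b)
  expect_equal(fit$baseline, mean(y) - b * mean(p))

  expect_equal(variance_explained(p, p)$ve, 1)
  expect_equal(variance_explained(y, c(1, 1, 1))$ve, 0)
  expect_true(variance_explained(c(2, 2, 2), p)$degenerate)
  # anticorrelated prediction scores 0 under the nonnegative-amplitude rule
  expect_equal(variance_explained(rev(y), p)$ve, 0)
  expect_equal(variance_explained(rev(y), p, nonneg = FALSE)$ve, r2)
})

test_that("variance explained is invariant to affine transforms of the data", {
  set.seed(7)
  for (i in 1:5) {
    y <- rnorm(40)
    p <- 0.5 * y + rnorm(40, 0, 0.5)
    v0 <- variance_explained(y, p)$ve
    expect_equal(variance_explained(3.2 * y - 7, p)$ve, v0)
    expect_equal(variance_explained(0.01 * y + 100, p)$ve, v0)
  }
})
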