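test_that("bar frames cover exactly the pixels inside the bar and field", {
  # degenerate full-cover: a 20-deg-wide bar blankets a 10-deg field
  f <- build_bar_frame(0, 0, width_deg = 20, radius_deg = 10, grid_n = 11L)
  coords <- seq(-10, 10, length.out = 11L)
  in_field <- outer(coords^2, coords^2, "+") <= 100
  expect_equal(f == 1, in_field)

  # bar outside the field is all zero
  expect_error(build_bar_frame(0, 14, 2, 10, 11L), "outside the field")
  f_edge <- build_bar_frame(0, 11.5, 2, 10, 11L)
  expect_true(all(f_edge == 0))

  expect_error(build_bar_frame(0, 0, -1, 10), "positive")
  expect_error(build_bar_frame(0, 0, 2, 0), "positive")

  # agreement with a per-pixel loop oracle across orientations and offsets
  for (ori in c(0, 30, 45, 90, 135)) {
    for (off in c(-4, 0, 2.5)) {
      expect_equal(build_bar_frame(ori, off, 2.75, 10.21, 21L),
                   bf_bar_frame(ori, off, 2.75, 10.21, 21L))
    }
  }
})

test_that("orthogonal and antipodal bar frames obey the grid symmetries", {
  for (off in c(-3, 0, 4.2)) {
    f0 <- build_bar_frame(0, off, 2.75, 10.21, 41L)
    f90 <- build_bar_frame(90, off, 2.75, 10.21, 41L)
    expect_equal(f90, t(f0))
  }
  # 180 deg rotation of direction with negated offset leaves the frame alone
  for (ori in c(0, 45, 90, 210)) {
    for (off in c(-5, 1.3)) {
      expect_equal(build_bar_frame(ori, off, 2.75, 10.21, 31L),
                   build_bar_frame(ori + 180, -off, 2.75, 10.21, 31L))
    }
  }
})

test_that("the canonical sweep sequence has 128 frames and four 12-s blanks", {
  m <- tiny_movie()
  expect_s3_class(m, "aperture_movie")
  expect_identical(n_frames(m), 128L)
  expect_equal(n_frames(m) * m$frame_duration_s, 192)

  zero <- apply(m$frames, 3L, sum) == 0
  expect_equal(sum(zero) * m$frame_duration_s, 48)  # 4 x 12 s
  runs <- rle(zero)
  blank_runs <- runs$lengths[runs$values]
  expect_identical(length(blank_runs), 4L)          # disjoint maximal runs
  expect_true(all(blank_runs * m$frame_duration_s == 12))

  expect_error(build_sweep_sequence(step_s = 1.7), "divisible")
})

test_that("hemifield masking halves cardinal-sweep coverage", {
  m <- tiny_movie()
  masked <- mask_hemifield(m, "left")
  # first sweep moves rightward (orientation 0): early frames sit in the kept
  # left hemifield, late frames are wiped entirely
  n_full <- apply(m$frames, 3L, sum)
  n_kept <- apply(masked$frames, 3L, sum)
  expect_true(all(n_kept <= n_full))
  expect_equal(n_kept[2:4], n_full[2:4])      # bar still left of fixation
  expect_true(all(n_kept[12:15] == 0))        # bar fully in the blanked side
  # vertical sweeps (frames 33-48, orientation 90) are split down the middle
  mid <- 33:48
  nonblank <- n_full[mid] > 0
  expect_true(all(abs(n_kept[mid][nonblank] / n_full[mid][nonblank] - 0.5) < 0.15))
})

test_that("scan timing reproduces the acquisition arithmetic", {
  st <- scan_timing(204, 1.5, 12)
  expect_identical(st$n_volumes, 136L)
  expect_identical(st$n_analyzed, 128L)
  expect_identical(st$n_missing_end_frames, 0L)

  expect_identical(scan_timing(192, 1.5, 0)$n_volumes, 128L)
  expect_identical(scan_timing(192, 1.5, 0)$n_analyzed, 128L)

  # truncated scan: 6 s of the cycle never recorded = 4 frames at 1.5 s
  st_short <- scan_timing(198, 1.5, 12)
  expect_identical(st_short$n_analyzed, 124L)
  expect_identical(st_short$n_missing_end_frames, 4L)

  expect_error(scan_timing(203, 1.5, 12), "multiples")
})

test_that("short-scan truncation drops exactly the unrecorded end frames", {
  m <- tiny_movie()
  m2 <- truncate_for_short_scan(m, 2L)
  expect_identical(n_frames(m2), 126L)
  expect_equal(m2$frames, m$frames[, , 1:126])

  expect_identical(truncate_for_short_scan(m, 0L), m)

  # the canonical sequence ends in a blank period, so dropped frames are zero
  m4 <- truncate_for_short_scan(m, 4L)
  dropped <- m$frames[, , 125:128]
  expect_true(all(dropped == 0))
  expect_error(truncate_for_short_scan(m, 128L), "n_missing")
})

test_that("frame count times duration equals cycle length across configs", {
  for (cfg in list(c(cycle = 192, step = 1.5, blank = 12),
                   c(cycle = 96, step = 1.5, blank = 6),
                   c(cycle = 192, step = 3, blank = 12))) {
    m <- build_sweep_sequence(step_s = cfg[["step"]], cycle_s = cfg[["cycle"]],
                              grid_n = 21L, blank_s = cfg[["blank"]])
    expect_equal(n_frames(m) * m$frame_duration_s, cfg[["cycle"]])
  }
})
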