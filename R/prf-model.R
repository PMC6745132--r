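#' pRF forward model
#'
#' A population receptive field is a 2D isotropic Gaussian in visual space
#' with centre `(x0, y0)` and size `sigma` (all in degrees). Its stimulus
#' drive at frame `t` is the pixel-area-weighted overlap of the Gaussian with
#' the binary aperture, which convolved with an HRF gives the predicted BOLD
#' series.
#'
#' @name prf-model
NULL

# Pixels-by-frames matrix, computed once per movie and cached on the object.
movie_pixel_matrix <- function(movie) {
  d <- dim(movie$frames)
  matrix(movie$frames, d[1L] * d[2L], d[3L])
}

# Gaussian field evaluated at every pixel of the movie grid, as a vector
# ordered like movie_pixel_matrix rows (column-major: y fastest).
pixel_gaussian <- function(movie, x0, y0, sigma) {
  gx <- exp(-(movie$grid_x - x0)^2 / (2 * sigma^2))
  gy <- exp(-(movie$grid_y - y0)^2 / (2 * sigma^2))
  as.vector(outer(gy, gx))  # rows y, columns x, column-major flatten
}

#' Per-frame overlap of a Gaussian pRF with the aperture movie
#'
#' `drive(t) = sum_pixels exp(-((x-x0)^2+(y-y0)^2) / (2 sigma^2)) S(t,x,y) a`
#' where `a` is the pixel area in deg^2; nonnegative by construction.
#'
#' @param x0,y0 pRF centre in degrees of visual angle.
#' @param sigma pRF size in degrees; must be positive.
#' @param movie an [aperture_movie()].
#' @return numeric vector, one drive value per frame.
#' @export
gaussian_aperture_overlap <- function(x0, y0, sigma, movie) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  g <- pixel_gaussian(movie, x0, y0, sigma)
  as.vector(crossprod(movie_pixel_matrix(movie), g)) * movie$pixel_area
}

#' Predicted BOLD series for a unilateral pRF
#'
#' Stimulus drive convolved with the HRF kernel and truncated to the analyzed
#' volume count. The movie must already be truncated for short scans; the
#' frame duration must equal the TR of `timing`.
#'
#' @param params list or named vector with `x0`, `y0`, `sigma`, and optionally
#'   `beta` (amplitude, default 1) and `baseline` (default 0).
#' @param movie an [aperture_movie()].
#' @param hrf sampled HRF kernel from [double_gamma_hrf()] at the movie's
#'   frame duration.
#' @param timing a [scan_timing()]; `n_analyzed` minus `n_missing_end_frames`
#'   must equal the movie's frame count.
#' @return numeric predicted series of length `n_frames(movie)`.
#' @export
prf_prediction <- function(params, movie, hrf, timing = NULL) {
  p <- as.list(params)
  drive <- gaussian_aperture_overlap(p$x0, p$y0, p$sigma, movie)
  predict_from_drive(drive, hrf, movie, timing, p)
}

#' Predicted BOLD series for a mirrored-bilateral pRF
#'
#' The drive is the sum of two equal-size, equal-amplitude Gaussians: one at
#' `(x0, y0)` and one mirrored about the horizontal meridian `(x0, -y0)` or
#' the vertical meridian `(-x0, y0)`. Sharing size and amplitude keeps the
#' parameter count identical to the unilateral model, so variance explained
#' is directly comparable between the two.
#'
#' @inheritParams prf_prediction
#' @param mirror_axis `"horizontal"` or `"vertical"`.
#' @export
bilateral_prediction <- function(params, mirror_axis = c("horizontal", "vertical"),
                                 movie, hrf, timing = NULL) {
  mirror_axis <- match.arg(mirror_axis)
  p <- as.list(params)
  m <- if (mirror_axis == "horizontal") c(p$x0, -p$y0) else c(-p$x0, p$y0)
  drive <- gaussian_aperture_overlap(p$x0, p$y0, p$sigma, movie) +
    gaussian_aperture_overlap(m[1L], m[2L], p$sigma, movie)
  predict_from_drive(drive, hrf, movie, timing, p)
}

predict_from_drive <- function(drive, hrf, movie, timing, p) {
  if (!is.null(timing)) {
    expected <- timing$n_analyzed - timing$n_missing_end_frames
    if (length(drive) != expected) {
      stop(sprintf(
        "movie has %d frames but timing expects %d analyzed volumes; truncate the movie first",
        length(drive), expected), call. = FALSE)
    }
  }
  beta <- if (is.null(p$beta)) 1 else p$beta
  baseline <- if (is.null(p$baseline)) 0 else p$baseline
  pred <- as.vector(convolve_columns(matrix(drive, ncol = 1L), hrf))
  beta * pred + baseline
}

#' Variance explained by a model prediction
#'
#' Proportion of variance in `data` captured by the least-squares fit of
#' `beta * prediction + baseline`, clipped to `[0, 1]`. With unconstrained
#' amplitude this is the squared Pearson correlation; with `nonneg = TRUE`
#' (the pRF convention — negative-going responses are out of scope) the
#' amplitude is constrained to `beta >= 0`, so anticorrelated predictions
#' score 0. Flat data or a flat prediction are degenerate and score 0.
#'
#' @param data observed series.
#' @param prediction model series of the same length (>= 3).
#' @param nonneg constrain the fitted amplitude to be nonnegative.
#' @return list: `ve`, `beta`, `baseline`, `degenerate`.
#' @export
variance_explained <- function(data, prediction, nonneg = TRUE) {
  stopifnot(length(data) == length(prediction), length(data) >= 3L)
  sd_d <- stats::sd(data)
  sd_p <- stats::sd(prediction)
  if (sd_d == 0 || sd_p == 0) {
    return(list(ve = 0, beta = 0, baseline = mean(data),
                degenerate = TRUE))
  }
  r <- stats::cor(data, prediction)
  beta <- r * sd_d / sd_p
  if (nonneg && beta < 0) {
    return(list(ve = 0, beta = 0, baseline = mean(data), degenerate = FALSE))
  }
  ve <- min(max(r^2, 0), 1)
  list(ve = ve, beta = beta,
       baseline = mean(data) - beta * mean(prediction),
       degenerate = FALSE)
}
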