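#' Additive noise specification
#'
#' Temporally autocorrelated Gaussian noise: an AR(1) process with stationary
#' standard deviation `sd` (signal units) and lag-one autocorrelation `ar1`.
#'
#' @param sd stationary noise SD (>= 0).
#' @param ar1 lag-one autocorrelation in `[0, 1)`; default 0.4.
#' @param seed RNG seed making the noise reproducible.
#' @export
noise_spec <- function(sd, ar1 = 0.4, seed = 1L) {
  stopifnot(sd >= 0, ar1 >= 0, ar1 < 1)
  structure(list(sd = sd, ar1 = ar1, seed = seed), class = "noise_spec")
}

# units x volumes matrix of AR(1) noise with stationary sd `spec$sd`.
ar1_noise <- function(n_units, n_volumes, spec) {
  if (spec$sd == 0) return(matrix(0, n_units, n_volumes))
  innov_sd <- spec$sd * sqrt(1 - spec$ar1^2)
  e <- matrix(stats::rnorm(n_units * n_volumes, 0, innov_sd),
              n_units, n_volumes)
  e[, 1L] <- stats::rnorm(n_units, 0, spec$sd)
  for (t in 2:n_volumes) e[, t] <- spec$ar1 * e[, t - 1L] + e[, t]
  e
}

#' Simulate a stimulus-driven (retinotopy) run
#'
#' Every vertex's noiseless series is the pRF forward prediction for its
#' ground-truth parameters; AR(1) noise is added on top. Vertices whose pRF
#' never overlaps the (possibly hemifield-masked) aperture produce a flat
#' series before noise.
#'
#' @param sheet,gt a sheet and ground-truth map from
#'   [make_visual_cortex_sheet()].
#' @param movie an [aperture_movie()] (truncate first for short scans).
#' @param hrf sampled HRF kernel at the movie frame duration.
#' @param noise a [noise_spec()].
#' @param vertices optional vertex ids to simulate (default: all).
#' @return matrix, vertices x volumes; rownames are vertex ids.
#' @export
simulate_active_run <- function(sheet, gt, movie, hrf,
                                noise = noise_spec(0), vertices = NULL) {
  g <- if (is.null(vertices)) gt else gt[gt$vertex %in% vertices, ]
  pred <- forward_predictions(g$x0, g$y0, g$sigma_prf, movie, hrf)
  with_seed(noise$seed, {
    out <- pred + ar1_noise(nrow(pred), ncol(pred), noise)
    rownames(out) <- g$vertex
    out
  })
}

# Noiseless pRF predictions for many vertices at once (vertices x volumes).
forward_predictions <- function(x0, y0, sigma, movie, hrf,
                                mirror_axis = NULL, mixing_weight = 0) {
  S <- movie_pixel_matrix(movie)
  nt <- ncol(S)
  G <- mapply(function(a, b, s) pixel_gaussian(movie, a, b, s), x0, y0, sigma)
  if (!is.null(mirror_axis) && mixing_weight > 0) {
    mx <- if (mirror_axis == "vertical") -x0 else x0
    my <- if (mirror_axis == "horizontal") -y0 else y0
    Gm <- mapply(function(a, b, s) pixel_gaussian(movie, a, b, s), mx, my, sigma)
    G <- G + mixing_weight * Gm
  }
  drives <- crossprod(S, G) * movie$pixel_area   # volumes x vertices
  t(convolve_columns(drives, hrf))
}

#' Simulate a resting-state run
#'
#' V1 receives latent signals that are spatially correlated (Gaussian kernel
#' of scale `latent_smoothness_mm` over geodesic distance) and temporally
#' low-pass filtered, then z-scored per vertex. Each target vertex's
#' noiseless series is exactly the connective-field forward model: the
#' Gaussian-CF-weighted sum of the observed V1 series at its true centre and
#' true `sigma_cf`. AR(1) noise is added to the targets; V1 is returned
#' noiseless so that, at noise sd 0, CF recovery is exact on the fitting
#' grid.
#'
#' @inheritParams simulate_active_run
#' @param n_volumes number of volumes (>= 30).
#' @param latent_smoothness_mm spatial correlation scale of the V1 latents in
#'   mm (default 5).
#' @return matrix, all sheet vertices x volumes; rownames are vertex ids.
#' @export
simulate_resting_run <- function(sheet, gt, n_volumes, latent_smoothness_mm = 5,
                                 noise = noise_spec(0)) {
  stopifnot(n_volumes >= 30)
  v1_ids <- sort(roi_vertices(sheet, "V1"))
  D <- roi_distance_matrix(sheet, "V1")
  stopifnot(identical(attr(D, "vertices"), v1_ids))
  K <- exp(-D^2 / (2 * latent_smoothness_mm^2))
  with_seed(noise$seed, {
    Z <- matrix(stats::rnorm(length(v1_ids) * n_volumes), length(v1_ids),
                n_volumes)
    L <- K %*% Z
    # temporal low-pass: 3-point moving average, reflected ends
    Lp <- t(apply(L, 1L, function(x) {
      xp <- c(x[1L], x, x[length(x)])
      (xp[1:(length(x))] + 2 * xp[2:(length(x) + 1L)] +
         xp[3:(length(x) + 2L)]) / 4
    }))
    V1 <- t(scale(t(Lp)))              # z-score per vertex
    rownames(V1) <- v1_ids

    tgt <- gt[gt$roi != "V1", ]
    preds <- matrix(0, nrow(tgt), n_volumes)
    for (i in seq_len(nrow(tgt))) {
      ci <- match(tgt$cf_center[i], v1_ids)
      w <- cf_kernel(D[ci, ], tgt$sigma_cf[i])
      preds[i, ] <- as.vector(crossprod(V1, w))
    }
    preds <- preds + ar1_noise(nrow(preds), n_volumes, noise)
    rownames(preds) <- tgt$vertex

    out <- rbind(V1, preds)
    out[order(as.integer(rownames(out))), , drop = FALSE]
  })
}

#' Simulate a subject with bilateral visual-field responses
#'
#' Each vertex responds to its ground-truth pRF plus the mirrored pRF
#' weighted by `mixing_weight`, then HRF convolution and AR(1) noise. With
#' `mixing_weight = 0` this reduces to [simulate_active_run()]; with weight 1
#' the matching mirrored-bilateral model is the generative model. The movie
#' must stimulate both hemifields for the bilateral component to be
#' identifiable.
#'
#' @inheritParams simulate_active_run
#' @param mirror_axis `"horizontal"` or `"vertical"`.
#' @param mixing_weight weight of the mirrored lobe in `[0, 1]`.
#' @export
simulate_bilateral_subject <- function(sheet, gt, movie, hrf,
                                       mirror_axis = c("horizontal", "vertical"),
                                       mixing_weight = 1,
                                       noise = noise_spec(0),
                                       vertices = NULL) {
  mirror_axis <- match.arg(mirror_axis)
  stopifnot(mixing_weight >= 0, mixing_weight <= 1)
  g <- if (is.null(vertices)) gt else gt[gt$vertex %in% vertices, ]
  pred <- forward_predictions(g$x0, g$y0, g$sigma_prf, movie, hrf,
                              mirror_axis = mirror_axis,
                              mixing_weight = mixing_weight)
  with_seed(noise$seed, {
    out <- pred + ar1_noise(nrow(pred), ncol(pred), noise)
    rownames(out) <- g$vertex
    out
  })
}

#' Reference signal SD of a noiseless active run
#'
#' Mean over stimulated vertices of the temporal SD of their noiseless pRF
#' predictions; the conventional yardstick when noise is expressed as a
#' fraction of signal ("sd = 0.2 x signal SD").
#'
#' @inheritParams simulate_active_run
#' @export
signal_sd <- function(sheet, gt, movie, hrf, vertices = NULL) {
  pred <- simulate_active_run(sheet, gt, movie, hrf, noise_spec(0),
                              vertices = vertices)
  sds <- apply(pred, 1L, stats::sd)
  mean(sds[sds > 0])
}
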