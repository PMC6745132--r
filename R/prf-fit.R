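#' Search-grid specification for pRF fitting
#'
#' Coarse-to-fine pRF estimation first evaluates every candidate on a grid of
#' centres and log-spaced sizes, then refines the best candidate with a
#' derivative-free local search. The grid covers `x0, y0` in
#' `[-field_radius, field_radius]` and `sigma` log-spaced over
#' `[sigma_min, sigma_max]`.
#'
#' @param field_radius_deg search-field radius in degrees.
#' @param n_xy grid points per centre axis (default 25).
#' @param n_sigma number of log-spaced sizes (default 12).
#' @param sigma_min,sigma_max size range in degrees (default 0.25 to the
#'   field radius).
#' @export
prf_grid_spec <- function(field_radius_deg, n_xy = 25L, n_sigma = 12L,
                          sigma_min = 0.25, sigma_max = field_radius_deg) {
  stopifnot(field_radius_deg > 0, n_xy >= 3L, n_sigma >= 2L,
            sigma_min > 0, sigma_max > sigma_min)
  structure(
    list(
      xs = seq(-field_radius_deg, field_radius_deg, length.out = n_xy),
      ys = seq(-field_radius_deg, field_radius_deg, length.out = n_xy),
      sigmas = exp(seq(log(sigma_min), log(sigma_max), length.out = n_sigma)),
      field_radius_deg = field_radius_deg
    ),
    class = "prf_grid_spec"
  )
}

# Grid predictions for one model kind: a T x n_candidates matrix plus the
# candidate table, ordered by (sigma, x0, y0) so that which.max() implements
# the tie-break toward smaller sigma then lexicographic (x0, y0).
prf_grid_predictions <- function(movie, hrf, grid_spec, model_kind) {
  xs <- grid_spec$xs; ys <- grid_spec$ys; sigmas <- grid_spec$sigmas
  S <- movie$frames
  nt <- dim(S)[3L]
  C <- hrf_toeplitz(hrf, nt)
  ny <- length(ys); nx <- length(xs)
  cand <- expand.grid(y0 = ys, x0 = xs, sigma = sigmas,
                      KEEP.OUT.ATTRS = FALSE)
  # candidate order: y0 fastest, then x0, then sigma -> sorted by (sigma, x0, y0)
  cand <- cand[, c("x0", "y0", "sigma")]
  P <- matrix(0, nt, nrow(cand))
  col0 <- 0L
  for (s in sigmas) {
    Gy <- exp(-outer(movie$grid_y, ys, "-")^2 / (2 * s^2))
    Gx <- exp(-outer(movie$grid_x, xs, "-")^2 / (2 * s^2))
    D <- array(0, dim = c(ny, nx, nt))
    for (t in seq_len(nt)) {
      D[, , t] <- crossprod(Gy, S[, , t] %*% Gx)
    }
    if (model_kind == "mirror_vertical")   D <- D + D[, nx:1L, , drop = FALSE]
    if (model_kind == "mirror_horizontal") D <- D + D[ny:1L, , , drop = FALSE]
    drives <- t(matrix(D, ny * nx, nt)) * movie$pixel_area
    P[, col0 + seq_len(ny * nx)] <- C %*% drives
    col0 <- col0 + ny * nx
  }
  list(candidates = cand, predictions = P)
}

prf_model_kinds <- c("unilateral", "mirror_horizontal", "mirror_vertical")

#' Fit 2D-Gaussian pRFs by grid search plus local refinement
#'
#' Maximises variance explained over a coarse grid of candidate centres and
#' sizes, then refines the winning candidate with a bounded Nelder-Mead
#' search on `(x0, y0, log sigma)`. The refined fit never scores below the
#' best grid fit. Amplitude is constrained nonnegative; the baseline is free.
#' Flat (zero-variance) series are flagged degenerate with `ve = 0`.
#'
#' @param ts numeric vector, or matrix with one row per unit
#'   (units x volumes).
#' @param movie an [aperture_movie()], already truncated for short scans.
#' @param hrf sampled HRF kernel at the movie frame duration.
#' @param timing optional [scan_timing()] cross-check.
#' @param grid_spec a [prf_grid_spec()]; defaults to the movie's field.
#' @param model_kind `"unilateral"`, `"mirror_horizontal"` or
#'   `"mirror_vertical"` (see [bilateral_prediction()]).
#' @param refine run the local refinement stage (default TRUE).
#' @param refine_maxit Nelder-Mead iteration cap per unit (default 100).
#' @return A tibble with one row per unit: `unit`, `model_kind`, `x0`, `y0`,
#'   `sigma`, `ecc`, `polar`, `beta`, `baseline`, `ve`, `degenerate`.
#' @export
fit_prf <- function(ts, movie, hrf, timing = NULL,
                    grid_spec = prf_grid_spec(movie$field_radius_deg),
                    model_kind = prf_model_kinds,
                    refine = TRUE, refine_maxit = 100L) {
  model_kind <- match.arg(model_kind)
  ts <- if (is.matrix(ts)) ts else matrix(ts, nrow = 1L)
  nt <- ncol(ts)
  if (nt != n_frames(movie)) {
    stop("time series length must equal the movie frame count", call. = FALSE)
  }
  if (!is.null(timing) &&
      nt != timing$n_analyzed - timing$n_missing_end_frames) {
    stop("time series length inconsistent with scan timing", call. = FALSE)
  }

  gp <- prf_grid_predictions(movie, hrf, grid_spec, model_kind)
  Z <- scale(gp$predictions)          # standardize candidates
  flat_cand <- !is.finite(colSums(Z)) | attr(Z, "scaled:scale") == 0
  Z[, flat_cand] <- 0

  data_sd <- apply(ts, 1L, stats::sd)
  Y <- t(ts)
  Ys <- scale(Y)
  Ys[, data_sd == 0] <- 0
  R <- crossprod(Ys, Z) / (nt - 1)    # units x candidates correlation
  VE <- pmax(R, 0)^2                  # beta >= 0 convention

  out <- vector("list", nrow(ts))
  for (v in seq_len(nrow(ts))) {
    y <- ts[v, ]
    if (data_sd[v] == 0) {
      out[[v]] <- prf_estimate_row(v, model_kind, NA, NA, NA, 0, mean(y),
                                   0, TRUE)
      next
    }
    best <- which.max(VE[v, ])
    par <- as.numeric(gp$candidates[best, ])
    best_ve <- VE[v, best]
    if (refine && best_ve > 0) {
      ref <- refine_prf(y, par, movie, hrf, model_kind, grid_spec,
                        refine_maxit)
      if (ref$ve >= best_ve) {
        par <- ref$par
        best_ve <- ref$ve
      }
    }
    fit <- variance_explained(
      y, prf_model_series(par, movie, hrf, model_kind), nonneg = TRUE)
    out[[v]] <- prf_estimate_row(v, model_kind, par[1L], par[2L], par[3L],
                                 fit$beta, fit$baseline, best_ve, FALSE)
  }
  do.call(rbind, out)
}

prf_estimate_row <- function(unit, model_kind, x0, y0, sigma, beta, baseline,
                             ve, degenerate) {
  tibble::tibble(
    unit = unit, model_kind = model_kind,
    x0 = x0, y0 = y0, sigma = sigma,
    ecc = sqrt(x0^2 + y0^2), polar = atan2(y0, x0),
    beta = beta, baseline = baseline, ve = ve, degenerate = degenerate
  )
}

prf_model_series <- function(par, movie, hrf, model_kind) {
  p <- list(x0 = par[1L], y0 = par[2L], sigma = par[3L])
  if (model_kind == "unilateral") {
    prf_prediction(p, movie, hrf)
  } else {
    axis <- sub("mirror_", "", model_kind)
    bilateral_prediction(p, axis, movie, hrf)
  }
}

refine_prf <- function(y, par0, movie, hrf, model_kind, grid_spec, maxit) {
  r <- grid_spec$field_radius_deg
  lo_s <- log(min(grid_spec$sigmas) / 4)
  hi_s <- log(max(grid_spec$sigmas) * 2)
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  obj <- function(theta) {
    x0 <- clamp(theta[1L], -r, r)
    y0 <- clamp(theta[2L], -r, r)
    sg <- exp(clamp(theta[3L], lo_s, hi_s))
    pred <- prf_model_series(c(x0, y0, sg), movie, hrf, model_kind)
    -variance_explained(y, pred, nonneg = TRUE)$ve
  }
  fit <- stats::optim(c(par0[1L], par0[2L], log(par0[3L])), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-6))
  list(par = c(clamp(fit$par[1L], -r, r), clamp(fit$par[2L], -r, r),
               exp(clamp(fit$par[3L], lo_s, hi_s))),
       ve = -fit$value)
}
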