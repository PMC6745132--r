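#' Connective-field prediction for one kernel
#'
#' A target vertex's prediction is the weighted sum of the source-ROI series
#' under a CF kernel; amplitude and offset are regressed against the target
#' when scoring (see [variance_explained()]).
#'
#' @param source_ts matrix, source vertices x volumes.
#' @param weights numeric kernel weights, one per source vertex.
#' @return numeric predicted series.
#' @export
cf_prediction <- function(source_ts, weights) {
  stopifnot(length(weights) == nrow(source_ts))
  as.vector(crossprod(source_ts, weights))
}

#' Default CF size search grid (mm)
#'
#' Spans sub-millimetre to very large fields, covering the range observed in
#' both stimulus-driven and resting-state CF maps (medians of a few mm with
#' tails above 9 mm); 0 is the delta kernel.
#' @export
cf_sigma_grid <- function() c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 20, 24, 30)

#' Fit connective fields by exhaustive search
#'
#' For every target vertex, maximises variance explained over all candidate
#' centre vertices in the source ROI crossed with a CF-size grid. Ties break
#' toward smaller `sigma_mm`, then lower centre vertex id. The estimate's
#' eccentricity is copied from the winning centre vertex's pRF map — CF
#' eccentricity is inherited, never re-fit. The identical engine serves
#' active-state and resting-state runs; only the input series differ.
#'
#' @param target_ts matrix (target vertices x volumes) or vector; rownames
#'   taken as target vertex ids when present.
#' @param source_ts matrix, source vertices x volumes; rownames must be the
#'   source vertex ids.
#' @param sheet a `cortical_sheet` providing the source submesh.
#' @param source_roi source ROI name (default `"V1"`).
#' @param sigma_grid candidate CF sizes in mm, sorted ascending; default
#'   [cf_sigma_grid()].
#' @param prf_ecc named numeric: pRF eccentricity per source vertex id
#'   (fitted or ground truth), inherited by the winning centre.
#' @param condition condition label recorded on the estimates: one of
#'   `"AS"`, `"RS"`, `"EO"`, `"EC"`, `"FIX"`.
#' @param target_roi optional ROI label recorded on the estimates.
#' @return tibble with one row per target: `unit`, `target_roi`, `condition`,
#'   `centre_vertex`, `sigma_mm`, `ecc`, `ve`, `degenerate`.
#' @export
fit_cf <- function(target_ts, source_ts, sheet, source_roi = "V1",
                   sigma_grid = cf_sigma_grid(), prf_ecc,
                   condition = c("AS", "RS", "EO", "EC", "FIX"),
                   target_roi = NA_character_) {
  condition <- match.arg(condition)
  if (length(sigma_grid) == 0L || is.unsorted(sigma_grid)) {
    stop("sigma_grid must be nonempty and sorted ascending", call. = FALSE)
  }
  target_ts <- if (is.matrix(target_ts)) target_ts else matrix(target_ts, 1L)
  src_ids <- sort(roi_vertices(sheet, source_roi))
  if (is.null(rownames(source_ts))) {
    stop("source_ts must carry vertex ids as rownames", call. = FALSE)
  }
  source_ts <- source_ts[match(as.character(src_ids), rownames(source_ts)), ,
                         drop = FALSE]
  if (anyNA(source_ts)) {
    stop("source_ts is missing series for some source-ROI vertices",
         call. = FALSE)
  }
  if (!all(as.character(src_ids) %in% names(prf_ecc))) {
    stop("prf_ecc must cover every source-ROI vertex", call. = FALSE)
  }
  D <- roi_distance_matrix(sheet, source_roi)
  stopifnot(identical(attr(D, "vertices"), src_ids))

  nt <- ncol(target_ts)
  tgt_sd <- apply(target_ts, 1L, stats::sd)
  Ys <- scale(t(target_ts))
  Ys[, tgt_sd == 0] <- 0

  n_tgt <- nrow(target_ts)
  best_ve <- rep(0, n_tgt)
  best_centre <- rep(src_ids[1L], n_tgt)
  best_sigma <- rep(sigma_grid[1L], n_tgt)
  for (s in sigma_grid) {
    W <- if (s == 0) diag(length(src_ids)) else exp(-D^2 / (2 * s^2))
    P <- W %*% source_ts                    # centres x volumes
    p_sd <- apply(P, 1L, stats::sd)
    Zp <- scale(t(P))
    Zp[, p_sd == 0] <- 0
    R2 <- (crossprod(Ys, Zp) / (nt - 1))^2   # targets x centres
    for (v in seq_len(n_tgt)) {
      j <- which.max(R2[v, ])                # first max -> lowest vertex id
      if (R2[v, j] > best_ve[v] + 1e-12) {   # strict: keep smaller sigma on ties
        best_ve[v] <- R2[v, j]
        best_centre[v] <- src_ids[j]
        best_sigma[v] <- s
      }
    }
  }
  units <- if (!is.null(rownames(target_ts))) as.integer(rownames(target_ts))
           else seq_len(n_tgt)
  degenerate <- tgt_sd == 0
  best_ve[degenerate] <- 0
  tibble::tibble(
    unit = units,
    target_roi = target_roi,
    condition = condition,
    centre_vertex = best_centre,
    sigma_mm = best_sigma,
    ecc = unname(prf_ecc[as.character(best_centre)]),
    ve = pmin(best_ve, 1),
    degenerate = degenerate
  )
}
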