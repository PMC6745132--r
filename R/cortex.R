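#' Simulated cortical sheet with labelled visual field maps
#'
#' The synthetic world every downstream stage is scored against: a planar
#' triangulated sheet for V1 plus one patch per target area, each vertex
#' carrying a ground-truth pRF, and each target vertex a ground-truth
#' connective field (CF) into V1.
#'
#' V1 is laid out as a retinotopic strip: log-eccentricity along one axis
#' (cortical magnification `u = 17 log(1 + ecc/0.75)` mm) and polar angle
#' along the other, covering a single hemifield — emulating the one remaining
#' hemisphere of a hemispherectomy case. True pRF size follows a linear
#' size-eccentricity law `sigma = intercept + slope * ecc`, scaled per area
#' by `area_size_factor`. Each target vertex's CF centre is the V1 vertex
#' with the nearest pRF centre; its CF size `sigma_cf` (mm) is set per area.
#'
#' @param n_v1_vertices requested V1 vertex count (>= 9); rounded up to the
#'   nearest complete grid.
#' @param vertices_per_target_area vertex count per target area (>= 9).
#' @param field_radius_deg maximum pRF eccentricity.
#' @param size_intercept_deg,size_slope_per_deg linear size-eccentricity law.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param target_areas character vector of target ROI names (default the six
#'   standard targets V2, V3, V3A, hV4, LO1, LO2).
#' @param area_size_factor multiplicative pRF-size factor per target area
#'   (recycled); V1 has factor 1.
#' @param cf_sigma_mm true CF size per target area in mm (recycled).
#' @param hemifield `"left"` or `"right"`: which hemifield the sheet
#'   represents.
#' @param ecc_min_deg smallest generated eccentricity (default 0.25).
#' @return list with `sheet` (class `cortical_sheet`: `vertices` tibble with
#'   `vertex`, `x_mm`, `y_mm`, `z_mm`, `roi`, `hemifield`; `triangles`
#'   integer matrix) and `gt` (class `ground_truth_map`: tibble with `vertex`,
#'   `roi`, `x0`, `y0`, `sigma_prf`, `cf_center`, `sigma_cf`, plus the seed).
#' @export
make_visual_cortex_sheet <- function(n_v1_vertices = 200L,
                                     vertices_per_target_area = 64L,
                                     field_radius_deg = 10.21,
                                     size_intercept_deg = 0.5,
                                     size_slope_per_deg = 0.15,
                                     seed = 1L,
                                     target_areas = c("V2", "V3", "V3A",
                                                      "hV4", "LO1", "LO2"),
                                     area_size_factor = c(1.5, 2, 2.5, 2.5, 3, 3),
                                     cf_sigma_mm = 3,
                                     hemifield = c("left", "right"),
                                     ecc_min_deg = 0.25) {
  hemifield <- match.arg(hemifield)
  if (n_v1_vertices < 9L || vertices_per_target_area < 9L) {
    stop("vertex counts must be >= 9 to triangulate", call. = FALSE)
  }
  stopifnot(field_radius_deg > 0, size_intercept_deg > 0,
            size_slope_per_deg >= 0)
  area_size_factor <- rep_len(area_size_factor, length(target_areas))
  cf_sigma_mm <- rep_len(cf_sigma_mm, length(target_areas))

  with_seed(seed, {
    v1 <- retinotopic_patch(n_v1_vertices, field_radius_deg, ecc_min_deg,
                            hemifield, jitter = 0)
    patches <- list(v1)
    for (i in seq_along(target_areas)) {
      p <- retinotopic_patch(vertices_per_target_area, field_radius_deg,
                             ecc_min_deg, hemifield, jitter = 0.04)
      p$vertices$x_mm <- p$vertices$x_mm + 60 * i   # disjoint patches
      patches[[i + 1L]] <- p
    }

    rois <- c("V1", target_areas)
    offset <- 0L
    verts <- list(); tris <- list(); gts <- list()
    for (i in seq_along(patches)) {
      p <- patches[[i]]
      nv <- nrow(p$vertices)
      verts[[i]] <- tibble::tibble(
        vertex = offset + seq_len(nv),
        x_mm = p$vertices$x_mm, y_mm = p$vertices$y_mm, z_mm = 0,
        roi = rois[i], hemifield = hemifield
      )
      tris[[i]] <- p$triangles + offset
      fac <- if (i == 1L) 1 else area_size_factor[i - 1L]
      gts[[i]] <- tibble::tibble(
        vertex = offset + seq_len(nv), roi = rois[i],
        x0 = p$vertices$x0, y0 = p$vertices$y0,
        sigma_prf = fac * (size_intercept_deg +
                             size_slope_per_deg * p$vertices$ecc),
        cf_center = NA_integer_,
        sigma_cf = if (i == 1L) NA_real_ else cf_sigma_mm[i - 1L]
      )
      offset <- offset + nv
    }
    vertices <- do.call(rbind, verts)
    gt <- do.call(rbind, gts)

    # CF centre: V1 vertex with the nearest ground-truth pRF centre
    v1_gt <- gt[gt$roi == "V1", ]
    tgt <- gt$roi != "V1"
    d2 <- outer(gt$x0[tgt], v1_gt$x0, "-")^2 + outer(gt$y0[tgt], v1_gt$y0, "-")^2
    gt$cf_center[tgt] <- v1_gt$vertex[max.col(-d2, ties.method = "first")]

    sheet <- structure(
      list(vertices = vertices, triangles = do.call(rbind, tris),
           hemifield = hemifield),
      class = "cortical_sheet"
    )
    gt <- structure(gt, class = c("ground_truth_map", class(gt)))
    attr(gt, "seed") <- seed
    attr(gt, "field_radius_deg") <- field_radius_deg
    list(sheet = sheet, gt = gt)
  })
}

# Rectangular retinotopic patch: grid in (log-ecc, polar-angle) space,
# optionally jittered, triangulated into grid quads. Returns visual-field
# coordinates of each vertex's pRF centre and planar mm positions.
retinotopic_patch <- function(n_vertices, field_radius_deg, ecc_min_deg,
                              hemifield, jitter = 0) {
  n_pol <- max(3L, floor(sqrt(n_vertices)))
  n_ecc <- max(3L, ceiling(n_vertices / n_pol))
  ecc <- exp(seq(log(ecc_min_deg), log(field_radius_deg), length.out = n_ecc))
  theta <- seq(-80, 80, length.out = n_pol) * pi / 180  # around horizontal
  g <- expand.grid(ie = seq_len(n_ecc), ip = seq_len(n_pol))
  e <- ecc[g$ie]
  th <- theta[g$ip]
  if (jitter > 0) {
    e <- pmin(pmax(e * exp(stats::rnorm(length(e), 0, jitter)), ecc_min_deg),
              field_radius_deg)
    th <- th + stats::rnorm(length(th), 0, jitter)
  }
  sgn <- if (hemifield == "left") -1 else 1
  vertices <- tibble::tibble(
    x_mm = 17 * log(1 + e / 0.75),    # magnification along eccentricity
    y_mm = 12 * th,                   # polar angle across the strip
    ecc = e,
    x0 = sgn * e * cos(th),
    y0 = e * sin(th)
  )
  tri <- grid_triangles(n_ecc, n_pol)
  list(vertices = vertices, triangles = tri)
}

grid_triangles <- function(n_ecc, n_pol) {
  idx <- function(ie, ip) (ip - 1L) * n_ecc + ie
  tris <- matrix(0L, 2L * (n_ecc - 1L) * (n_pol - 1L), 3L)
  k <- 0L
  for (ip in seq_len(n_pol - 1L)) {
    for (ie in seq_len(n_ecc - 1L)) {
      a <- idx(ie, ip); b <- idx(ie + 1L, ip)
      c <- idx(ie, ip + 1L); d <- idx(ie + 1L, ip + 1L)
      tris[k + 1L, ] <- c(a, b, d)
      tris[k + 2L, ] <- c(a, d, c)
      k <- k + 2L
    }
  }
  tris
}

#' @export
print.cortical_sheet <- function(x, ...) {
  cat(sprintf("cortical_sheet: %d vertices, %d triangles, %s hemifield\n",
              nrow(x$vertices), nrow(x$triangles), x$hemifield))
  print(table(x$vertices$roi))
  invisible(x)
}

# Evaluate an expression with a locally-set RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

roi_vertices <- function(sheet, roi) {
  sheet$vertices$vertex[sheet$vertices$roi %in% roi]
}
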