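# Shared fixtures and independent oracles. Expensive objects are memoised in
# the test session so individual files stay fast.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

tiny_movie <- function(grid_n = 41L) {
  memo(paste0("movie", grid_n), build_sweep_sequence(grid_n = grid_n))
}

tiny_hrf <- function() memo("hrf", double_gamma_hrf(1.5))

small_world <- function(seed = 3L, n_v1 = 64L, n_target = 16L,
                        targets = c("V2", "V3A"), cf_sigma = 3) {
  memo(paste0("world", seed, n_v1, n_target, cf_sigma),
       make_visual_cortex_sheet(
         n_v1_vertices = n_v1, vertices_per_target_area = n_target,
         seed = seed, target_areas = targets,
         area_size_factor = c(1.5, 2.5), cf_sigma_mm = cf_sigma))
}

# --- independent oracles -------------------------------------------------

# Bar frame by straightforward per-pixel loop.
bf_bar_frame <- function(orientation_deg, offset_deg, width_deg, radius_deg,
                         grid_n) {
  coords <- seq(-radius_deg, radius_deg, length.out = grid_n)
  out <- matrix(0, grid_n, grid_n)
  th <- orientation_deg * pi / 180
  for (iy in seq_len(grid_n)) {
    for (ix in seq_len(grid_n)) {
      x <- coords[ix]; y <- coords[iy]
      u <- x * cos(th) + y * sin(th)
      if (abs(u - offset_deg) <= width_deg / 2 && x^2 + y^2 <= radius_deg^2) {
        out[iy, ix] <- 1
      }
    }
  }
  out
}

# Gaussian-aperture drive with the same binary aperture but the Gaussian
# integrated on a k x k subpixel lattice within every pixel.
subpixel_overlap <- function(x0, y0, sigma, frame, coords, k = 10L) {
  d <- coords[2L] - coords[1L]
  subs <- seq(-d / 2 + d / (2 * k), d / 2 - d / (2 * k), length.out = k)
  fx <- vapply(coords, function(cx)
    sum(exp(-(cx + subs - x0)^2 / (2 * sigma^2))), numeric(1L)) / k
  fy <- vapply(coords, function(cy)
    sum(exp(-(cy + subs - y0)^2 / (2 * sigma^2))), numeric(1L)) / k
  sum(outer(fy, fx) * frame) * d^2
}

# All-pairs shortest paths by Floyd-Warshall on an edge-weight matrix.
bf_floyd_warshall <- function(W) {
  n <- nrow(W)
  D <- W
  D[D == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# One-sample t statistic from first principles.
bf_one_sample_t <- function(x, mu = 0) {
  n <- length(x)
  (mean(x) - mu) / (sd(x) / sqrt(n))
}

# Hand-made 6-vertex chain sheet with 1-mm edges (two thin triangles per
# segment keep it a valid mesh; the apex row is offset far away so shortest
# paths run along the chain).
chain_sheet <- function(n = 6L, edge_mm = 1) {
  vertices <- tibble::tibble(
    vertex = seq_len(2L * n),
    x_mm = c(seq_len(n) - 1, seq_len(n) - 1) * edge_mm,
    y_mm = rep(c(0, 100), each = n),
    z_mm = 0,
    roi = "V1",
    hemifield = "left"
  )
  tris <- matrix(0L, 2L * (n - 1L), 3L)
  for (i in seq_len(n - 1L)) {
    tris[2L * i - 1L, ] <- c(i, i + 1L, n + i)
    tris[2L * i, ] <- c(i + 1L, n + i, n + i + 1L)
  }
  structure(list(vertices = vertices, triangles = tris, hemifield = "left"),
            class = "cortical_sheet")
}

# Small planar grid sheet for geodesic oracle comparisons.
grid_sheet <- function(nx = 5L, ny = 4L, spacing = 1) {
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  vertices <- tibble::tibble(
    vertex = seq_len(nrow(g)),
    x_mm = (g$ix - 1) * spacing, y_mm = (g$iy - 1) * spacing, z_mm = 0,
    roi = "V1", hemifield = "left"
  )
  idx <- function(ix, iy) (iy - 1L) * nx + ix
  tris <- list()
  for (iy in seq_len(ny - 1L)) {
    for (ix in seq_len(nx - 1L)) {
      tris[[length(tris) + 1L]] <- c(idx(ix, iy), idx(ix + 1L, iy),
                                     idx(ix + 1L, iy + 1L))
      tris[[length(tris) + 1L]] <- c(idx(ix, iy), idx(ix + 1L, iy + 1L),
                                     idx(ix, iy + 1L))
    }
  }
  structure(list(vertices = vertices, triangles = do.call(rbind, tris),
                 hemifield = "left"),
            class = "cortical_sheet")
}
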