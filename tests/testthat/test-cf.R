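test_that("geodesic distances sum edge lengths along a chain", {
  sh <- chain_sheet(6L, edge_mm = 1)
  gf <- geodesic_distances(sh, "V1", 1L)
  expect_s3_class(gf, "geodesic_field")
  expect_equal(gf$distances_mm[gf$vertices == 1L], 0)
  expect_equal(gf$distances_mm[gf$vertices == 6L], 5)

  expect_error(geodesic_distances(sh, "V1", 999L), "not in ROI")
})

test_that("geodesics match a Floyd-Warshall oracle and are metric", {
  sh <- grid_sheet(5L, 4L)
  n <- nrow(sh$vertices)
  # adjacency with Euclidean weights straight from the triangle edges
  W <- matrix(0, n, n)
  tri <- sh$triangles
  p <- as.matrix(sh$vertices[, c("x_mm", "y_mm", "z_mm")])
  for (r in seq_len(nrow(tri))) {
    for (pair in list(tri[r, 1:2], tri[r, 2:3], tri[r, c(1L, 3L)])) {
      w <- sqrt(sum((p[pair[1L], ] - p[pair[2L], ])^2))
      W[pair[1L], pair[2L]] <- W[pair[2L], pair[1L]] <- w
    }
  }
  D_or <- bf_floyd_warshall(W)
  for (c0 in c(1L, 7L, 20L)) {
    gf <- geodesic_distances(sh, "V1", c0)
    d <- gf$distances_mm[order(gf$vertices)]
    expect_equal(d, D_or[c0, ])
  }
  # symmetry and triangle inequality on sampled triples
  set.seed(5)
  for (i in 1:20) {
    abc <- sample(n, 3L)
    expect_equal(D_or[abc[1L], abc[2L]], D_or[abc[2L], abc[1L]])
    expect_lte(D_or[abc[1L], abc[3L]],
               D_or[abc[1L], abc[2L]] + D_or[abc[2L], abc[3L]] + 1e-12)
  }
})

test_that("disconnected source ROIs are reported with the unreachable vertices", {
  sh <- grid_sheet(3L, 3L)
  far <- chain_sheet(3L)
  far$vertices$vertex <- far$vertices$vertex + 100L
  far$triangles <- far$triangles + 100L
  both <- structure(
    list(vertices = rbind(sh$vertices, far$vertices),
         triangles = rbind(sh$triangles, far$triangles),
         hemifield = "left"),
    class = "cortical_sheet")
  expect_error(geodesic_distances(both, "V1", 1L), "disconnected")
})

test_that("the CF kernel is Gaussian in cortical distance with a delta limit", {
  d <- c(0, 1, 2, 3, 5)
  w <- cf_kernel(d, 2)
  expect_equal(w[1L], 1)
  expect_equal(cf_kernel(2, 2), exp(-0.5))
  w0 <- cf_kernel(d, 0)
  expect_equal(w0, c(1, 0, 0, 0, 0))
  expect_error(cf_kernel(d, -1), ">= 0")
})

test_that("CF predictions are weighted sums of the source series", {
  set.seed(8)
  src <- matrix(rnorm(5 * 40), 5, 40)
  w1 <- c(0, 0, 2, 0, 0)
  expect_equal(cf_prediction(src, w1), 2 * src[3L, ])
  wu <- rep(1, 5)
  expect_equal(cf_prediction(src, wu), colSums(src))
})

test_that("noiseless resting-state CF fits recover the generative kernel", {
  w <- small_world()
  rs <- simulate_resting_run(w$sheet, w$gt, 80, 5, noise_spec(0, seed = 6))
  v1 <- sort(w$gt$vertex[w$gt$roi == "V1"])
  tgt <- w$gt[w$gt$roi != "V1", ]
  ecc <- setNames(sqrt(w$gt$x0^2 + w$gt$y0^2), w$gt$vertex)[as.character(v1)]
  cf <- fit_cf(rs[as.character(tgt$vertex), ], rs[as.character(v1), ],
               w$sheet, prf_ecc = ecc, condition = "RS")
  expect_true(all(cf$centre_vertex == tgt$cf_center))
  # true sigma (3 mm) lies on the default grid
  expect_true(all(cf$sigma_mm == 3))
  expect_true(all(cf$ve > 0.999))
  # eccentricity is copied bit-for-bit from the centre's pRF value
  expect_identical(cf$ecc, unname(ecc[as.character(cf$centre_vertex)]))
})

test_that("a target equal to one source series triggers the delta kernel", {
  w <- small_world()
  rs <- simulate_resting_run(w$sheet, w$gt, 60, 5, noise_spec(0, seed = 9))
  v1 <- sort(w$gt$vertex[w$gt$roi == "V1"])
  ecc <- setNames(sqrt(w$gt$x0^2 + w$gt$y0^2), w$gt$vertex)[as.character(v1)]
  pick <- v1[7L]
  target <- rs[as.character(pick), , drop = FALSE]
  rownames(target) <- "999"
  cf <- fit_cf(target, rs[as.character(v1), ], w$sheet, prf_ecc = ecc,
               condition = "RS")
  expect_equal(cf$centre_vertex, pick)
  expect_equal(cf$sigma_mm, min(cf_sigma_grid()))
})

test_that("refining the sigma grid never lowers the fitted variance explained", {
  w <- small_world()
  rs <- simulate_resting_run(w$sheet, w$gt, 60, 5, noise_spec(1, seed = 10))
  v1 <- sort(w$gt$vertex[w$gt$roi == "V1"])
  tgt_ids <- w$gt$vertex[w$gt$roi != "V1"][1:10]
  ecc <- setNames(sqrt(w$gt$x0^2 + w$gt$y0^2), w$gt$vertex)[as.character(v1)]
  coarse_grid <- c(0, 2, 6, 12)
  fine_grid <- sort(c(coarse_grid, 1, 3, 4, 8))
  coarse <- fit_cf(rs[as.character(tgt_ids), ], rs[as.character(v1), ],
                   w$sheet, sigma_grid = coarse_grid, prf_ecc = ecc,
                   condition = "RS")
  fine <- fit_cf(rs[as.character(tgt_ids), ], rs[as.character(v1), ],
                 w$sheet, sigma_grid = fine_grid, prf_ecc = ecc,
                 condition = "RS")
  expect_true(all(fine$ve >= coarse$ve - 1e-10))

  # flat target series are degenerate, not errors
  flat <- matrix(1, 1L, 60)
  rownames(flat) <- "999"
  cf_flat <- fit_cf(flat, rs[as.character(v1), ], w$sheet, prf_ecc = ecc,
                    condition = "RS")
  expect_true(cf_flat$degenerate)
  expect_equal(cf_flat$ve, 0)
  expect_error(fit_cf(flat, rs[as.character(v1), ], w$sheet,
                      sigma_grid = numeric(0), prf_ecc = ecc),
               "nonempty")
})
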