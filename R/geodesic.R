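#' Geodesic distances on the cortical mesh
#'
#' Cortical distance is measured as shortest-path length over the mesh edge
#' graph with Euclidean edge weights, restricted to one ROI's submesh — the
#' standard approximation used for connective-field kernels at typical mesh
#' resolutions.
#'
#' @name geodesic
NULL

# Undirected edge list (pairs of vertex ids) of an ROI's submesh.
roi_edge_graph <- function(sheet, roi) {
  keep <- roi_vertices(sheet, roi)
  tri <- sheet$triangles
  in_roi <- matrix(tri %in% keep, nrow(tri), 3L)
  tri <- tri[rowSums(in_roi) == 3L, , drop = FALSE]
  if (nrow(tri) == 0L) stop(sprintf("ROI '%s' has no triangles", roi),
                            call. = FALSE)
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1L, 3L)])
  edges <- unique(t(apply(edges, 1L, sort)))
  v <- sheet$vertices
  p <- as.matrix(v[, c("x_mm", "y_mm", "z_mm")])
  rownames(p) <- v$vertex
  w <- sqrt(rowSums((p[as.character(edges[, 1L]), , drop = FALSE] -
                       p[as.character(edges[, 2L]), , drop = FALSE])^2))
  if (any(w <= 0)) stop("mesh contains zero-length edges", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1L]),
               to = as.character(edges[, 2L]), weight = w),
    directed = FALSE,
    vertices = data.frame(name = as.character(keep))
  )
  g
}

#' Single-source geodesic distances within an ROI
#'
#' @param sheet a `cortical_sheet`.
#' @param source_roi ROI name; the centre must belong to it and its submesh
#'   must be connected.
#' @param centre_vertex vertex id of the field centre.
#' @return `geodesic_field`: list with `centre_vertex`, `vertices` (ids in
#'   graph order) and `distances_mm`.
#' @export
geodesic_distances <- function(sheet, source_roi, centre_vertex) {
  keep <- roi_vertices(sheet, source_roi)
  if (!centre_vertex %in% keep) {
    stop(sprintf("centre vertex %d is not in ROI '%s'", centre_vertex,
                 source_roi), call. = FALSE)
  }
  g <- roi_edge_graph(sheet, source_roi)
  d <- igraph::distances(g, v = as.character(centre_vertex))[1L, ]
  if (any(!is.finite(d))) {
    bad <- names(d)[!is.finite(d)]
    stop(sprintf("ROI '%s' is disconnected; unreachable vertices: %s",
                 source_roi, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(centre_vertex = centre_vertex,
         vertices = as.integer(names(d)),
         distances_mm = unname(d)),
    class = "geodesic_field"
  )
}

# All-pairs geodesic distances within an ROI, rows/cols in vertex-id order.
roi_distance_matrix <- function(sheet, roi) {
  g <- roi_edge_graph(sheet, roi)
  D <- igraph::distances(g)
  ids <- as.integer(rownames(D))
  ord <- order(ids)
  D <- D[ord, ord]
  if (any(!is.finite(D))) {
    stop(sprintf("ROI '%s' is disconnected", roi), call. = FALSE)
  }
  attr(D, "vertices") <- ids[ord]
  D
}

#' Gaussian connective-field kernel over cortical distance
#'
#' `w(v) = exp(-d(v)^2 / (2 sigma_mm^2))`; the limit `sigma_mm = 0` is the
#' delta kernel: weight 1 at the centre, 0 elsewhere.
#'
#' @param field a [geodesic_distances()] result, or a numeric distance vector.
#' @param sigma_mm CF size in mm (>= 0).
#' @return numeric weights, one per source vertex.
#' @export
cf_kernel <- function(field, sigma_mm) {
  if (sigma_mm < 0) stop("sigma_mm must be >= 0", call. = FALSE)
  d <- if (inherits(field, "geodesic_field")) field$distances_mm else field
  if (sigma_mm == 0) return(as.numeric(d == 0))
  exp(-d^2 / (2 * sigma_mm^2))
}
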