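#' Read and write analysis artefacts
#'
#' Round-trip adapters for the pipeline's tables and arrays: estimate tables
#' and time series as CSV, time-series stacks and aperture movies as NIfTI,
#' run configs as YAML, and run reports as JSON. Write-then-read reproduces
#' values to full precision (CSV numerics are serialised with 17 significant
#' digits).
#'
#' @name visurf-io
NULL

estimate_table_schema <- c("subject", "group", "unit", "roi", "area_group",
                           "condition", "param", "value", "ecc", "ve")

#' @rdname visurf-io
#' @param table an [estimate_table()].
#' @param path file path.
#' @export
write_estimate_table <- function(table, path) {
  missing <- setdiff(estimate_table_schema, names(table))
  if (length(missing)) {
    stop("estimate table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  write_csv_full(table[, estimate_table_schema], path)
}

#' @rdname visurf-io
#' @export
read_estimate_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(estimate_table_schema, names(tb))
  if (length(missing)) {
    stop("estimate table at ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(tb$roi),
                 c("V1", "V2", "V3", "V3A", "hV4", "LO1", "LO2", "none"))
  if (length(bad)) {
    stop("unknown ROI label(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tb
}

write_csv_full <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 17,
                                               trim = TRUE, scientific = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' @rdname visurf-io
#' @param ts matrix, units x volumes, rownames as unit ids.
#' @export
write_timeseries_csv <- function(ts, path) {
  df <- data.frame(unit = rownames(ts) %||% seq_len(nrow(ts)),
                   unclass(as.data.frame(ts)))
  names(df) <- c("unit", paste0("t", seq_len(ncol(ts))))
  write_csv_full(df, path)
}

#' @rdname visurf-io
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1L] != "unit") stop("time-series CSV must start with a 'unit' column",
                                    call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$unit
  dimnames(m)[[2L]] <- NULL
  m
}

#' @rdname visurf-io
#' @export
write_timeseries_nifti <- function(ts, path) {
  arr <- array(ts, dim = c(nrow(ts), 1L, 1L, ncol(ts)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname visurf-io
#' @export
read_timeseries_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  matrix(arr, dim(arr)[1L], dim(arr)[4L])
}

#' @rdname visurf-io
#' @param movie an [aperture_movie()].
#' @export
write_aperture_nifti <- function(movie, path) {
  img <- RNifti::asNifti(movie$frames)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname visurf-io
#' @param frame_duration_s,field_radius_deg movie metadata (NIfTI stores the
#'   array only).
#' @export
read_aperture_nifti <- function(path, frame_duration_s, field_radius_deg) {
  arr <- RNifti::readNifti(path)
  aperture_movie(round(array(arr, dim(arr))), frame_duration_s,
                 field_radius_deg)
}

#' @rdname visurf-io
#' @param sheet a `cortical_sheet`.
#' @param dir output directory; writes `vertices.csv` and `triangles.csv`.
#' @export
write_sheet_csv <- function(sheet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_full(sheet$vertices, file.path(dir, "vertices.csv"))
  utils::write.csv(as.data.frame(sheet$triangles), file.path(dir, "triangles.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname visurf-io
#' @export
read_sheet_csv <- function(dir) {
  vertices <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "vertices.csv"), stringsAsFactors = FALSE))
  need <- c("vertex", "x_mm", "y_mm", "z_mm", "roi", "hemifield")
  missing <- setdiff(need, names(vertices))
  if (length(missing)) {
    stop("sheet vertices.csv missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(vertices$roi),
                 c("V1", "V2", "V3", "V3A", "hV4", "LO1", "LO2", "none"))
  if (length(bad)) {
    stop("unknown ROI label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  triangles <- as.matrix(utils::read.csv(file.path(dir, "triangles.csv")))
  dimnames(triangles) <- NULL
  structure(list(vertices = vertices, triangles = triangles,
                 hemifield = vertices$hemifield[1L]),
            class = "cortical_sheet")
}

#' @rdname visurf-io
#' @param gt a `ground_truth_map`.
#' @export
write_ground_truth_csv <- function(gt, path) {
  write_csv_full(as.data.frame(gt), path)
}

#' @rdname visurf-io
#' @param report a run report list.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname visurf-io
#' @param config a run-config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname visurf-io
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

`%||%` <- function(a, b) if (is.null(a)) b else a
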