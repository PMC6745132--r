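#' Binary drifting-bar aperture movies
#'
#' An `aperture_movie` holds the binary stimulus masks that the pRF forward
#' model integrates over: a stack of square frames sampled on a pixel grid in
#' degrees of visual angle, centred on fixation. The canonical retinotopy
#' sequence is a bar sweeping the visual field in eight directions with four
#' 12-s mean-luminance ("blank") periods replacing the diagonal sweeps' final
#' segments.
#'
#' @param frames numeric array, `grid_n x grid_n x n_frames`, entries 0/1;
#'   rows index y (increasing upward), columns index x (increasing rightward).
#' @param frame_duration_s seconds each frame is on screen.
#' @param field_radius_deg stimulated field radius in degrees of visual angle.
#' @return An object of class `aperture_movie`: list with `frames`,
#'   `frame_duration_s`, `field_radius_deg`, `grid_x`, `grid_y` (pixel-centre
#'   coordinates in deg) and `pixel_area` (deg^2).
#' @export
aperture_movie <- function(frames, frame_duration_s, field_radius_deg) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[1L] != dim(frames)[2L]) {
    stop("aperture frames must be square", call. = FALSE)
  }
  if (!all(frames %in% c(0, 1))) {
    stop("aperture frames must be binary (0/1)", call. = FALSE)
  }
  if (frame_duration_s <= 0 || field_radius_deg <= 0) {
    stop("frame duration and field radius must be positive", call. = FALSE)
  }
  grid_n <- dim(frames)[1L]
  coords <- grid_coords(field_radius_deg, grid_n)
  structure(
    list(
      frames = frames,
      frame_duration_s = frame_duration_s,
      field_radius_deg = field_radius_deg,
      grid_x = coords,
      grid_y = coords,
      pixel_area = (coords[2L] - coords[1L])^2
    ),
    class = "aperture_movie"
  )
}

grid_coords <- function(radius_deg, grid_n) {
  stopifnot(grid_n >= 3L)
  seq(-radius_deg, radius_deg, length.out = grid_n)
}

#' @export
print.aperture_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "aperture_movie: %d frames of %dx%d px, %.3g s/frame, field radius %.3g deg (%.4g s total)\n",
    d[3L], d[1L], d[2L], x$frame_duration_s, x$field_radius_deg,
    d[3L] * x$frame_duration_s
  ))
  invisible(x)
}

#' Number of frames in an aperture movie
#' @param movie an [aperture_movie()].
#' @export
n_frames <- function(movie) dim(movie$frames)[3L]

#' Build one bar aperture frame
#'
#' The bar is perpendicular to the motion direction `orientation_deg` and its
#' centre line sits `offset_deg` along that direction from fixation. Pixels
#' within `width_deg / 2` of the centre line and within `radius_deg` of
#' fixation are set to 1.
#'
#' @param orientation_deg motion direction in degrees (0 = rightward, 90 = up).
#' @param offset_deg signed distance of the bar centre line from fixation
#'   along the motion axis.
#' @param width_deg bar width in degrees; must be positive.
#' @param radius_deg stimulated field radius; must be positive.
#' @param grid_n pixels per side (>= 3).
#' @return `grid_n x grid_n` binary matrix (rows = y, columns = x).
#' @export
build_bar_frame <- function(orientation_deg, offset_deg, width_deg, radius_deg,
                            grid_n = 101L) {
  if (width_deg <= 0 || radius_deg <= 0) {
    stop("width_deg and radius_deg must be positive", call. = FALSE)
  }
  stopifnot(grid_n >= 3L)
  if (abs(offset_deg) > radius_deg + width_deg) {
    stop("offset places the bar entirely outside the field", call. = FALSE)
  }
  coords <- grid_coords(radius_deg, grid_n)
  x <- matrix(coords, grid_n, grid_n, byrow = TRUE)
  y <- matrix(coords, grid_n, grid_n, byrow = FALSE)
  theta <- orientation_deg * pi / 180
  u <- x * cos(theta) + y * sin(theta)
  frame <- (abs(u - offset_deg) <= width_deg / 2) & (x^2 + y^2 <= radius_deg^2)
  storage.mode(frame) <- "double"
  frame
}

#' Build the canonical eight-sweep drifting-bar sequence
#'
#' Eight sweeps of equal duration tile one stimulus cycle; the bar steps every
#' `step_s` seconds from one field edge to the opposite one along each motion
#' direction in `sweep_order`. During each diagonal sweep the final `blank_s`
#' seconds are replaced by mean-luminance (all-zero) frames, giving four
#' disjoint blank periods per cycle.
#'
#' @param radius_deg,width_deg bar geometry in degrees; the default is the
#'   control-group geometry (radius 10.21, width 2.75); the case geometry is
#'   radius 12, width 3.
#' @param step_s motion step, seconds per frame (default 1.5).
#' @param cycle_s full cycle duration (default 192); must be divisible by
#'   `step_s` and by 8 sweeps.
#' @param grid_n pixels per side (default 101).
#' @param blank_s blank-period duration inserted at the end of each diagonal
#'   sweep (default 12); must be divisible by `step_s`.
#' @param sweep_order motion directions in degrees; default alternates
#'   cardinal and diagonal. Order is configurable because only aperture
#'   coverage, not order, affects fitted parameters under a linear model.
#' @return An [aperture_movie()] with `cycle_s / step_s` frames.
#' @export
build_sweep_sequence <- function(radius_deg = 10.21, width_deg = 2.75,
                                 step_s = 1.5, cycle_s = 192, grid_n = 101L,
                                 blank_s = 12,
                                 sweep_order = c(0, 45, 90, 135, 180, 225, 270, 315)) {
  n_sweeps <- length(sweep_order)
  if (!isTRUE(all.equal(cycle_s %% step_s, 0)) ||
      !isTRUE(all.equal((cycle_s / n_sweeps) %% step_s, 0)) ||
      !isTRUE(all.equal(blank_s %% step_s, 0))) {
    stop("cycle_s, cycle_s/n_sweeps and blank_s must be divisible by step_s",
         call. = FALSE)
  }
  frames_per_sweep <- as.integer(round(cycle_s / n_sweeps / step_s))
  n_blank <- as.integer(round(blank_s / step_s))
  if (n_blank >= frames_per_sweep) {
    stop("blank period longer than a sweep", call. = FALSE)
  }
  total <- as.integer(round(cycle_s / step_s))
  frames <- array(0, dim = c(grid_n, grid_n, total))
  offsets <- seq(-radius_deg, radius_deg, length.out = frames_per_sweep)
  is_diag <- (sweep_order %% 90) != 0
  k <- 0L
  for (s in seq_len(n_sweeps)) {
    for (f in seq_len(frames_per_sweep)) {
      k <- k + 1L
      if (is_diag[s] && f > frames_per_sweep - n_blank) next  # blank frame
      frames[, , k] <- build_bar_frame(sweep_order[s], offsets[f], width_deg,
                                       radius_deg, grid_n)
    }
  }
  aperture_movie(frames, step_s, radius_deg)
}

#' Mask an aperture movie to one hemifield
#'
#' Zeroes every pixel on the suppressed side of the vertical meridian,
#' emulating hemianopic stimulation (only one hemifield drives responses).
#'
#' @param movie an [aperture_movie()].
#' @param keep which hemifield remains stimulated: `"left"` (x < 0) or
#'   `"right"` (x > 0). Pixels at x = 0 are kept either way.
#' @export
mask_hemifield <- function(movie, keep = c("left", "right")) {
  keep <- match.arg(keep)
  drop_cols <- if (keep == "left") movie$grid_x > 0 else movie$grid_x < 0
  frames <- movie$frames
  frames[, drop_cols, ] <- 0
  aperture_movie(frames, movie$frame_duration_s, movie$field_radius_deg)
}

#' Scan-timing bookkeeping
#'
#' Converts scan duration, repetition time and prescan period into volume
#' counts, and records how many stimulus frames at the end of the cycle were
#' never recorded when the scanner stopped early (as happens for truncated
#' scans); predictions must then be shortened to match via
#' [truncate_for_short_scan()].
#'
#' @param duration_s total scan duration; must be an exact multiple of `tr_s`.
#' @param tr_s repetition time in seconds.
#' @param prescan_s discarded prescan period; must be a multiple of `tr_s`.
#' @param cycle_s stimulus cycle length used to detect truncated scans
#'   (default 192).
#' @param frame_s stimulus frame duration (default `tr_s`).
#' @return `scan_timing` list: `duration_s`, `tr_s`, `prescan_s`,
#'   `n_volumes`, `n_analyzed`, `n_missing_end_frames`.
#' @examples
#' scan_timing(204, 1.5, 12)  # 136 volumes, 128 analyzed
#' @export
scan_timing <- function(duration_s, tr_s, prescan_s, cycle_s = 192,
                        frame_s = tr_s) {
  if (tr_s <= 0) stop("tr_s must be positive", call. = FALSE)
  if (!isTRUE(all.equal(duration_s %% tr_s, 0)) ||
      !isTRUE(all.equal(prescan_s %% tr_s, 0))) {
    stop("duration_s and prescan_s must be exact multiples of tr_s",
         call. = FALSE)
  }
  n_volumes <- as.integer(round(duration_s / tr_s))
  n_analyzed <- n_volumes - as.integer(round(prescan_s / tr_s))
  missing_s <- max(0, prescan_s + cycle_s - duration_s)
  structure(
    list(
      duration_s = duration_s, tr_s = tr_s, prescan_s = prescan_s,
      n_volumes = n_volumes, n_analyzed = n_analyzed,
      n_missing_end_frames = as.integer(round(missing_s / frame_s))
    ),
    class = "scan_timing"
  )
}

#' Drop unrecorded end-of-cycle frames from a movie
#'
#' For scans that stopped before the stimulus cycle finished, the model
#' prediction must cover only the recorded volumes; this drops the final
#' `n_missing_end_frames` frames.
#'
#' @param movie an [aperture_movie()].
#' @param n_missing_end_frames number of trailing frames to drop; must be
#'   smaller than the frame count.
#' @export
truncate_for_short_scan <- function(movie, n_missing_end_frames) {
  nf <- n_frames(movie)
  if (n_missing_end_frames < 0 || n_missing_end_frames >= nf) {
    stop("n_missing_end_frames must be in [0, n_frames)", call. = FALSE)
  }
  if (n_missing_end_frames == 0) return(movie)
  keep <- seq_len(nf - n_missing_end_frames)
  aperture_movie(movie$frames[, , keep, drop = FALSE],
                 movie$frame_duration_s, movie$field_radius_deg)
}
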