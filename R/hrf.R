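#' Haemodynamic response function specification
#'
#' Canonical two-gamma HRF: a positive response peaking at `peak_delay_s`
#' followed by a smaller undershoot peaking at `undershoot_delay_s`, with the
#' undershoot scaled by `ratio`. Dispersion parameters control the width of
#' each gamma lobe.
#'
#' @param peak_delay_s time-to-peak of the positive lobe (s), default 5.4.
#' @param undershoot_delay_s time-to-peak of the undershoot (s), default 10.8.
#' @param peak_disp,undershoot_disp dispersion (s) of each lobe, default 0.9.
#' @param ratio undershoot : peak amplitude ratio, default 0.35.
#' @param length_s kernel support in seconds (>= 24), default 32.
#' @export
hrf_spec <- function(peak_delay_s = 5.4, undershoot_delay_s = 10.8,
                     peak_disp = 0.9, undershoot_disp = 0.9,
                     ratio = 0.35, length_s = 32) {
  if (peak_disp <= 0 || undershoot_disp <= 0) {
    stop("dispersion parameters must be positive", call. = FALSE)
  }
  if (peak_delay_s <= 0 || undershoot_delay_s <= 0 || ratio < 0) {
    stop("invalid HRF parameters", call. = FALSE)
  }
  if (length_s < 24) stop("kernel length must be >= 24 s", call. = FALSE)
  structure(
    list(peak_delay_s = peak_delay_s, undershoot_delay_s = undershoot_delay_s,
         peak_disp = peak_disp, undershoot_disp = undershoot_disp,
         ratio = ratio, length_s = length_s),
    class = "hrf_spec"
  )
}

#' Sample a two-gamma HRF kernel
#'
#' Each lobe is `(t/d)^(d/b) * exp(-(t-d)/b)` (unit height at its own peak
#' `d`, dispersion `b`); the undershoot is subtracted with weight `ratio`.
#' The sampled kernel is peak-normalised to a maximum of 1.
#'
#' @param tr_s sampling interval in seconds; must be positive.
#' @param spec an [hrf_spec()].
#' @return numeric kernel sampled at `0, tr_s, 2 tr_s, ...` up to `length_s`.
#' @export
double_gamma_hrf <- function(tr_s, spec = hrf_spec()) {
  if (tr_s <= 0) stop("tr_s must be positive", call. = FALSE)
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$length_s, by = tr_s)
  lobe <- function(d, b) ifelse(t <= 0, 0, (t / d)^(d / b) * exp(-(t - d) / b))
  h <- lobe(spec$peak_delay_s, spec$peak_disp) -
    spec$ratio * lobe(spec$undershoot_delay_s, spec$undershoot_disp)
  if (sum(h) <= 0) stop("degenerate HRF: kernel does not integrate to a positive value",
                        call. = FALSE)
  h / max(h)
}

# Causal convolution of each column of `x` (time along rows) with kernel `h`,
# truncated to the input length. Implemented as one banded lower-triangular
# matrix product so that fitting loops amortise the kernel.
convolve_columns <- function(x, h) {
  x <- as.matrix(x)
  n <- nrow(x)
  C <- hrf_toeplitz(h, n)
  C %*% x
}

hrf_toeplitz <- function(h, n) {
  C <- matrix(0, n, n)
  for (k in seq_along(h)) {
    if (k > n) break
    idx <- seq_len(n - k + 1L)
    C[cbind(idx + k - 1L, idx)] <- h[k]
  }
  C
}
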