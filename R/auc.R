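#' Isosensitivity curve between two variance-explained distributions
#'
#' Sweeps the VE threshold from `threshold_lo` to `threshold_hi`; at each
#' threshold the HIT rate is the fraction of the test distribution at or
#' above it and the FA rate the fraction of the baseline distribution at or
#' above it. Both distributions must already be restricted to units where
#' all compared models reach the entry VE threshold, so the same unit set is
#' evaluated for every model.
#'
#' @param ve_test,ve_baseline VE values of the test and baseline model.
#' @param threshold_lo,threshold_hi sweep range, default 0.20 to 0.99.
#' @param n_thresholds number of evenly spaced thresholds, default 80.
#' @return `iso_curve` list: `thresholds`, `hit`, `fa` (each non-increasing
#'   in threshold).
#' @export
isosensitivity <- function(ve_test, ve_baseline, threshold_lo = 0.20,
                           threshold_hi = 0.99, n_thresholds = 80L) {
  stopifnot(length(ve_test) > 0, length(ve_baseline) > 0,
            threshold_hi > threshold_lo, n_thresholds >= 2L)
  th <- seq(threshold_lo, threshold_hi, length.out = n_thresholds)
  structure(
    list(
      thresholds = th,
      hit = vapply(th, function(t) mean(ve_test >= t), numeric(1L)),
      fa = vapply(th, function(t) mean(ve_baseline >= t), numeric(1L))
    ),
    class = "iso_curve"
  )
}

# Trapezoidal area under the isosensitivity curve anchored at (0,0) and (1,1).
iso_auc <- function(curve) {
  fa <- c(0, rev(curve$fa), 1)
  hit <- c(0, rev(curve$hit), 1)
  ord <- order(fa, hit)
  fa <- fa[ord]; hit <- hit[ord]
  sum(diff(fa) * (utils::head(hit, -1L) + utils::tail(hit, -1L)) / 2)
}

#' AUC model comparison with bootstrap confidence interval
#'
#' Area under the anchored isosensitivity curve: 0.5 means the two models
#' explain the data equally well, above 0.5 the test model wins, below 0.5
#' the baseline wins. The 95% CI comes from resampling both VE distributions
#' with replacement. The decision field applies an Occam's-razor rule when
#' the test model is the more complex one: adopt the simpler (baseline)
#' model unless the AUC is significantly above 0.5 (CI entirely above 0.5).
#'
#' @inheritParams isosensitivity
#' @param n_boot bootstrap draws, default 2000.
#' @param level confidence level, default 0.95.
#' @param seed RNG seed.
#' @return `auc_result` list: `auc`, `ci_lo`, `ci_hi`, `n_boot`, `seed`,
#'   `curve`, `decision` (`"test"` or `"baseline"`).
#' @export
auc_with_ci <- function(ve_test, ve_baseline, n_boot = 2000L, level = 0.95,
                        seed = 1L, threshold_lo = 0.20, threshold_hi = 0.99,
                        n_thresholds = 80L) {
  curve <- isosensitivity(ve_test, ve_baseline, threshold_lo, threshold_hi,
                          n_thresholds)
  auc <- iso_auc(curve)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bt <- sample(ve_test, length(ve_test), replace = TRUE)
    bb <- sample(ve_baseline, length(ve_baseline), replace = TRUE)
    iso_auc(isosensitivity(bt, bb, threshold_lo, threshold_hi, n_thresholds))
  }, numeric(1L)))
  ci <- unname(stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
  structure(
    list(auc = auc, ci_lo = ci[1L], ci_hi = ci[2L], n_boot = n_boot,
         seed = seed, curve = curve,
         decision = if (ci[1L] > 0.5) "test" else "baseline"),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f [%.4f, %.4f] (%d bootstrap draws) -> adopt %s model\n",
              x$auc, x$ci_lo, x$ci_hi, x$n_boot, x$decision))
  invisible(x)
}
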