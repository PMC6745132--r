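#' Tidy per-unit estimate tables
#'
#' Every statistic in the case-versus-controls layer consumes a tidy table
#' with one row per (subject, unit, condition, parameter) carrying the
#' estimate `value`, the unit's eccentricity and the model's variance
#' explained. ROIs are grouped into early (V1, V2, V3) and late (V3A, hV4,
#' LO1, LO2) visual areas.
#'
#' @param subject subject identifier.
#' @param group `"patient"` or `"control"`.
#' @param unit unit (voxel/vertex) id.
#' @param roi ROI name.
#' @param condition condition label (`"AS"`, `"RS"`, `"EO"`, `"EC"`, `"FIX"`).
#' @param param parameter kind: `"prf_ecc"`, `"prf_size"`, `"cf_ecc"`,
#'   `"cf_size"`.
#' @param value the estimate (deg for eccentricities/pRF sizes, mm for CF
#'   sizes).
#' @param ecc the unit's eccentricity in deg (used by the eccentricity cap).
#' @param ve variance explained of the generating model fit.
#' @return tibble with the above columns plus `area_group`.
#' @export
estimate_table <- function(subject, group, unit, roi, condition, param,
                           value, ecc, ve) {
  tb <- tibble::tibble(
    subject = subject, group = group, unit = unit, roi = roi,
    area_group = area_group_of(roi),
    condition = condition, param = param,
    value = value, ecc = ecc, ve = ve
  )
  if (any(!is.finite(tb$value))) {
    stop("estimate values must be finite", call. = FALSE)
  }
  tb
}

#' Early/late visual-area grouping
#' @param roi character vector of ROI names.
#' @return `"early"` for V1, V2, V3; `"late"` for V3A, hV4, LO1, LO2;
#'   `NA` otherwise.
#' @export
area_group_of <- function(roi) {
  out <- rep(NA_character_, length(roi))
  out[roi %in% c("V1", "V2", "V3")] <- "early"
  out[roi %in% c("V3A", "hV4", "LO1", "LO2")] <- "late"
  out
}

#' Variance-explained and eccentricity thresholds
#'
#' Keeps rows with `ve >= ve_min` (inclusive) and `ecc <= ecc_max` (values
#' larger than the cap are excluded), preserving row order. Idempotent by
#' construction. An empty result warns rather than errors.
#'
#' @param table an [estimate_table()] (any data frame with `ve` and `ecc`).
#' @param ve_min VE threshold, default 0.20.
#' @param ecc_max eccentricity cap in deg, default 10.2.
#' @export
apply_thresholds <- function(table, ve_min = 0.20, ecc_max = 10.2) {
  stopifnot(nrow(table) > 0)
  out <- table[table$ve >= ve_min & table$ecc <= ecc_max, , drop = FALSE]
  if (nrow(out) == 0L) warning("no estimates survive the thresholds")
  out
}

#' Percentile-bootstrap confidence interval of the median
#'
#' @param values numeric vector (>= 2 values).
#' @param n_iter bootstrap iterations, default 1000.
#' @param level confidence level, default 0.95.
#' @param seed RNG seed; results are reproducible given the seed.
#' @return numeric `c(low, high)`.
#' @export
bootstrap_median_ci <- function(values, n_iter = 1000L, level = 0.95,
                                seed = 1L) {
  stopifnot(length(values) >= 2L)
  with_seed(seed, {
    meds <- vapply(seq_len(n_iter), function(i) {
      stats::median(sample(values, length(values), replace = TRUE))
    }, numeric(1L))
    unname(stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' Eccentricity-binned median sizes with bootstrap CIs
#'
#' Bins eccentricity into contiguous `bin_deg`-wide bins starting at 0 and
#' reports the median size per bin with its percentile-bootstrap confidence
#' interval. Empty bins are excluded (and thereby excluded from trend fits).
#'
#' @param ecc unit eccentricities in deg.
#' @param size the corresponding sizes (deg or mm).
#' @param bin_deg bin width in deg, default 1.
#' @param n_iter,level,seed bootstrap settings, see [bootstrap_median_ci()].
#' @return `binned_medians` tibble: `bin_lo`, `bin_hi`, `bin_mid`, `n`,
#'   `median`, `ci_lo`, `ci_hi`.
#' @export
binned_median_size <- function(ecc, size, bin_deg = 1.0, n_iter = 1000L,
                               level = 0.95, seed = 1L) {
  stopifnot(length(ecc) == length(size), bin_deg > 0)
  idx <- floor(ecc / bin_deg)
  rows <- lapply(sort(unique(idx)), function(b) {
    v <- size[idx == b]
    ci <- if (length(v) >= 2L) {
      bootstrap_median_ci(v, n_iter, level, seed = seed + b)
    } else c(v, v)
    tibble::tibble(
      bin_lo = b * bin_deg, bin_hi = (b + 1) * bin_deg,
      bin_mid = (b + 0.5) * bin_deg, n = length(v),
      median = stats::median(v), ci_lo = ci[1L], ci_hi = ci[2L]
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("binned_medians", class(out))
  out
}

#' Linear size-eccentricity trend on binned medians
#'
#' Ordinary least squares of the per-bin median size on bin-centre
#' eccentricity (the default); `method = "l1"` instead minimises the sum of
#' absolute residuals (median regression) by direct search, reported without
#' standard errors.
#'
#' @param binned a [binned_median_size()] result with >= 3 bins.
#' @param method `"ols"` (default) or `"l1"`.
#' @return `trend_fit` list: `slope`, `intercept`, `p_value` (slope), `df`,
#'   `method`.
#' @export
fit_size_ecc_trend <- function(binned, method = c("ols", "l1")) {
  method <- match.arg(method)
  if (nrow(binned) < 3L) stop("need >= 3 nonempty bins for a trend fit",
                              call. = FALSE)
  if (method == "ols") {
    fit <- stats::lm(median ~ bin_mid, data = binned)
    # suppress the "essentially perfect fit" note: exact lines are legitimate
    sm <- suppressWarnings(summary(fit))$coefficients
    out <- list(slope = unname(stats::coef(fit)[2L]),
                intercept = unname(stats::coef(fit)[1L]),
                p_value = unname(sm["bin_mid", "Pr(>|t|)"]),
                df = stats::df.residual(fit), method = "ols")
  } else {
    l1 <- function(b) sum(abs(binned$median - b[1L] - b[2L] * binned$bin_mid))
    start <- stats::coef(stats::lm(median ~ bin_mid, data = binned))
    fit <- stats::optim(unname(start), l1, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    out <- list(slope = fit$par[2L], intercept = fit$par[1L],
                p_value = NA_real_, df = nrow(binned) - 2L, method = "l1")
  }
  structure(out, class = "trend_fit")
}

#' Slope difference between two binned series
#'
#' Fits both series jointly and tests the group-by-eccentricity interaction
#' with an F-test; `delta_slope = slope_a - slope_b` exactly equals the
#' difference of the single-series OLS slopes.
#'
#' @param binned_a,binned_b two [binned_median_size()] results (>= 3 bins
#'   each).
#' @return `trend_fit` list with `slope_a`, `slope_b`, `delta_slope`,
#'   `f_statistic`, `p_value`, `df1`, `df2`.
#' @export
compare_trends <- function(binned_a, binned_b) {
  if (nrow(binned_a) < 3L || nrow(binned_b) < 3L) {
    stop("need >= 3 nonempty bins per series", call. = FALSE)
  }
  dat <- rbind(
    data.frame(median = binned_a$median, ecc = binned_a$bin_mid, grp = "a"),
    data.frame(median = binned_b$median, ecc = binned_b$bin_mid, grp = "b")
  )
  full <- stats::lm(median ~ ecc * grp, data = dat)
  reduced <- stats::lm(median ~ ecc + grp, data = dat)
  an <- stats::anova(reduced, full)
  slope_a <- fit_size_ecc_trend(binned_a)$slope
  slope_b <- fit_size_ecc_trend(binned_b)$slope
  structure(
    list(slope_a = slope_a, slope_b = slope_b,
         delta_slope = slope_a - slope_b,
         f_statistic = an$F[2L], p_value = an$`Pr(>F)`[2L],
         df1 = an$Df[2L], df2 = an$Res.Df[2L]),
    class = "trend_fit"
  )
}

#' Relative frequency distribution
#'
#' Histogram normalised to sum to 1, over contiguous bins of `bin_width`
#' aligned at 0. `max_value` fixes the upper edge so distributions from
#' different subjects share edges before averaging.
#'
#' @param values nonnegative values (deg or mm).
#' @param bin_width bin width (0.5 deg for eccentricities and pRF sizes,
#'   0.5 mm for CF sizes).
#' @param max_value upper edge; default the smallest multiple of `bin_width`
#'   covering the data.
#' @return tibble: `bin_lo`, `bin_hi`, `bin_mid`, `freq`.
#' @export
relative_frequency <- function(values, bin_width, max_value = NULL) {
  stopifnot(bin_width > 0, length(values) > 0)
  if (is.null(max_value)) max_value <- ceiling(max(values) / bin_width) * bin_width
  edges <- seq(0, max_value, by = bin_width)
  if (max(values) > max_value || min(values) < 0) {
    stop("values fall outside [0, max_value]", call. = FALSE)
  }
  counts <- graphics::hist(values, breaks = edges, plot = FALSE,
                           right = FALSE, include.lowest = TRUE)$counts
  tibble::tibble(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
    bin_mid = (edges[-length(edges)] + edges[-1L]) / 2,
    freq = counts / sum(counts)
  )
}

#' Mean relative-frequency distribution across subjects
#'
#' Averages per-subject histograms (which must share bin edges) and attaches
#' the normal-theory (t-based) 95% CI of the per-bin mean.
#'
#' @param histograms list of [relative_frequency()] tibbles with identical
#'   edges.
#' @param level confidence level, default 0.95.
#' @return tibble: `bin_lo`, `bin_hi`, `bin_mid`, `mean_freq`, `ci_lo`,
#'   `ci_hi`.
#' @export
group_mean_distribution <- function(histograms, level = 0.95) {
  stopifnot(length(histograms) >= 1L)
  edges <- histograms[[1L]][, c("bin_lo", "bin_hi")]
  for (h in histograms) {
    if (!isTRUE(all.equal(h[, c("bin_lo", "bin_hi")], edges,
                          check.attributes = FALSE))) {
      stop("histograms must share bin edges before averaging", call. = FALSE)
    }
  }
  M <- do.call(rbind, lapply(histograms, function(h) h$freq))
  n <- nrow(M)
  m <- colMeans(M)
  se <- if (n > 1L) apply(M, 2L, stats::sd) / sqrt(n) else rep(0, ncol(M))
  tq <- if (n > 1L) stats::qt(1 - (1 - level) / 2, df = n - 1L) else 0
  tibble::tibble(
    bin_lo = histograms[[1L]]$bin_lo, bin_hi = histograms[[1L]]$bin_hi,
    bin_mid = histograms[[1L]]$bin_mid,
    mean_freq = m, ci_lo = m - tq * se, ci_hi = m + tq * se
  )
}

#' One-sample t-test on patient-minus-control median differences
#'
#' Difference scores `patient - control_i` for every control are tested
#' against zero; significance uses a Bonferroni-corrected alpha (default
#' 0.0125 for a four-comparison family).
#'
#' @param patient_median the patient's median for the parameter.
#' @param control_medians per-control medians (>= 2).
#' @param alpha_corrected corrected significance level, default 0.0125.
#' @return `diff_test` list: `mean_diff`, `t`, `df`, `p_value`,
#'   `alpha_corrected`, `significant`, `degenerate`.
#' @export
case_vs_controls_median_test <- function(patient_median, control_medians,
                                         alpha_corrected = 0.0125) {
  stopifnot(length(control_medians) >= 2L)
  d <- patient_median - control_medians
  if (stats::sd(d) == 0) {
    return(structure(
      list(mean_diff = mean(d), t = NA_real_, df = length(d) - 1L,
           p_value = NA_real_, alpha_corrected = alpha_corrected,
           significant = NA, degenerate = TRUE),
      class = "diff_test"))
  }
  tt <- stats::t.test(d, mu = 0)
  structure(
    list(mean_diff = mean(d), t = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         alpha_corrected = alpha_corrected,
         significant = tt$p.value < alpha_corrected, degenerate = FALSE),
    class = "diff_test"
  )
}

#' Paired t-test between two viewing conditions
#'
#' Restricts both vectors to the shared-unit mask (units passing the VE
#' threshold in both conditions) before testing; out-of-mask values can
#' never influence the result. p-values are reported uncorrected for spatial
#' autocorrelation, as is conventional for these comparisons.
#'
#' @param values_a,values_b per-unit values in the two conditions (equal
#'   length).
#' @param mask logical mask of units to compare.
#' @param alpha significance level, default 0.05.
#' @return `diff_test` list: `mean_diff`, `t`, `df`, `p_value`,
#'   `alpha_corrected`, `significant`, `degenerate`, `n_pairs`.
#' @export
paired_condition_test <- function(values_a, values_b, mask, alpha = 0.05) {
  stopifnot(length(values_a) == length(values_b),
            length(mask) == length(values_a))
  a <- values_a[mask]; b <- values_b[mask]
  if (length(a) < 2L) stop("need >= 2 shared units", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(structure(
      list(mean_diff = mean(d), t = if (all(d == 0)) 0 else NA_real_,
           df = length(d) - 1L, p_value = if (all(d == 0)) 1 else NA_real_,
           alpha_corrected = alpha, significant = FALSE, degenerate = TRUE,
           n_pairs = length(d)),
      class = "diff_test"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(
    list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         alpha_corrected = alpha, significant = tt$p.value < alpha,
         degenerate = FALSE, n_pairs = length(d)),
    class = "diff_test"
  )
}
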