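#' Default end-to-end run configuration
#'
#' A fully serialisable list describing one simulate-fit-analyze run: a run
#' is reproducible from its config plus seed alone. The default is
#' demo-scale (a small sheet, two target areas, a 61-px aperture grid) so a
#' full pipeline finishes in minutes on one CPU; the per-field documentation
#' gives the full-scale values used for the package's headline analyses.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @return nested list with components `stimulus`, `cortex`, `noise`,
#'   `resting`, `fit`, `stats`, `n_controls`, `model_comparison`, `seed`.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_controls = 3L,
    model_comparison = TRUE,
    stimulus = list(radius_deg = 10.21, width_deg = 2.75, step_s = 1.5,
                    cycle_s = 192, grid_n = 61L, blank_s = 12),
    cortex = list(n_v1_vertices = 64L, vertices_per_target_area = 25L,
                  size_intercept_deg = 0.5, size_slope_per_deg = 0.15,
                  target_areas = c("V2", "V3"),
                  area_size_factor = c(1.5, 2),
                  cf_sigma_mm = 3, patient_cf_scale = 2,
                  hemifield = "left"),
    noise = list(sd_frac = 0.2, ar1 = 0.4),
    resting = list(n_volumes = 120L, latent_smoothness_mm = 5),
    fit = list(n_xy = 15L, n_sigma = 8L, refine = TRUE, refine_maxit = 40L),
    stats = list(ve_min = 0.20, ecc_max = 10.2, bin_deg = 1.0,
                 n_boot_median = 1000L, hist_bin = 0.5,
                 alpha_corrected = 0.0125, auc_n_boot = 2000L)
  )
}

#' Run the full simulate-fit-analyze pipeline
#'
#' Executes, in order: stimulus construction; synthetic cortex + active and
#' resting runs for one hemianopic "patient" (hemifield-masked stimulus,
#' enlarged true CFs) and `n_controls` control subjects; unilateral pRF fits
#' for every vertex; CF fits from V1 for the active-state and resting-state
#' runs; thresholding; the group statistics layer; and (optionally) the
#' unilateral-versus-bilateral model comparison on patient V1. Reruns with
#' the same config produce identical outputs.
#'
#' @param config a config list from [default_run_config()] (possibly
#'   modified).
#' @param out_dir optional directory: estimate tables are written as CSV and
#'   the report as `report.json`.
#' @return run-report list: `config`, `estimates` (tidy table), per-group
#'   medians, median-difference tests, binned trends, relative-frequency
#'   distributions, model-comparison AUCs, and any empty-result warnings.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  st <- config$stimulus
  movie <- build_sweep_sequence(st$radius_deg, st$width_deg, st$step_s,
                                st$cycle_s, st$grid_n, st$blank_s)
  hrf <- double_gamma_hrf(st$step_s)
  grid <- prf_grid_spec(st$radius_deg, config$fit$n_xy, config$fit$n_sigma)

  subjects <- c("patient", paste0("control", seq_len(config$n_controls)))
  est_rows <- list()
  patient_v1 <- NULL
  warnings_seen <- character()

  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    is_patient <- sid == "patient"
    cx <- config$cortex
    sub_seed <- config$seed * 1000L + i
    world <- make_visual_cortex_sheet(
      n_v1_vertices = cx$n_v1_vertices,
      vertices_per_target_area = cx$vertices_per_target_area,
      field_radius_deg = st$radius_deg,
      size_intercept_deg = cx$size_intercept_deg,
      size_slope_per_deg = cx$size_slope_per_deg,
      seed = sub_seed,
      target_areas = cx$target_areas,
      area_size_factor = cx$area_size_factor,
      cf_sigma_mm = cx$cf_sigma_mm *
        if (is_patient) cx$patient_cf_scale else 1,
      hemifield = cx$hemifield
    )
    sub_movie <- if (is_patient) mask_hemifield(movie, cx$hemifield) else movie
    sig <- signal_sd(world$sheet, world$gt, sub_movie, hrf)
    nz <- noise_spec(config$noise$sd_frac * sig, config$noise$ar1,
                     seed = sub_seed + 1L)
    as_run <- simulate_active_run(world$sheet, world$gt, sub_movie, hrf, nz)
    rs_run <- simulate_resting_run(world$sheet, world$gt,
                                   config$resting$n_volumes,
                                   config$resting$latent_smoothness_mm,
                                   noise_spec(config$noise$sd_frac,
                                              config$noise$ar1,
                                              seed = sub_seed + 2L))

    prf <- fit_prf(as_run, sub_movie, hrf, grid_spec = grid,
                   model_kind = "unilateral",
                   refine = config$fit$refine,
                   refine_maxit = config$fit$refine_maxit)
    prf$vertex <- as.integer(rownames(as_run))
    prf$roi <- world$sheet$vertices$roi[match(prf$vertex,
                                              world$sheet$vertices$vertex)]
    v1_ids <- sort(roi_vertices(world$sheet, "V1"))
    prf_ecc <- stats::setNames(prf$ecc, prf$vertex)[as.character(v1_ids)]
    tgt_ids <- world$gt$vertex[world$gt$roi != "V1"]
    tgt_rois <- world$gt$roi[world$gt$roi != "V1"]

    cf_as <- fit_cf(as_run[as.character(tgt_ids), , drop = FALSE],
                    as_run[as.character(v1_ids), , drop = FALSE],
                    world$sheet, "V1", prf_ecc = prf_ecc, condition = "AS")
    cf_rs <- fit_cf(rs_run[as.character(tgt_ids), , drop = FALSE],
                    rs_run[as.character(v1_ids), , drop = FALSE],
                    world$sheet, "V1", prf_ecc = prf_ecc, condition = "RS")
    cf_as$target_roi <- cf_rs$target_roi <- tgt_rois

    grp <- if (is_patient) "patient" else "control"
    est_rows[[length(est_rows) + 1L]] <- rbind(
      estimate_table(sid, grp, prf$vertex, prf$roi, "AS", "prf_ecc",
                     prf$ecc, prf$ecc, prf$ve),
      estimate_table(sid, grp, prf$vertex, prf$roi, "AS", "prf_size",
                     prf$sigma, prf$ecc, prf$ve),
      estimate_table(sid, grp, cf_as$unit, cf_as$target_roi, "AS", "cf_ecc",
                     cf_as$ecc, cf_as$ecc, cf_as$ve),
      estimate_table(sid, grp, cf_as$unit, cf_as$target_roi, "AS", "cf_size",
                     cf_as$sigma_mm, cf_as$ecc, cf_as$ve),
      estimate_table(sid, grp, cf_rs$unit, cf_rs$target_roi, "RS", "cf_ecc",
                     cf_rs$ecc, cf_rs$ecc, cf_rs$ve),
      estimate_table(sid, grp, cf_rs$unit, cf_rs$target_roi, "RS", "cf_size",
                     cf_rs$sigma_mm, cf_rs$ecc, cf_rs$ve)
    )

    if (is_patient && isTRUE(config$model_comparison)) {
      v1_ts <- as_run[as.character(v1_ids), , drop = FALSE]
      patient_v1 <- list(
        uni = fit_prf(v1_ts, sub_movie, hrf, grid_spec = grid,
                      model_kind = "unilateral",
                      refine = config$fit$refine,
                      refine_maxit = config$fit$refine_maxit),
        mh = fit_prf(v1_ts, sub_movie, hrf, grid_spec = grid,
                     model_kind = "mirror_horizontal",
                     refine = config$fit$refine,
                     refine_maxit = config$fit$refine_maxit),
        mv = fit_prf(v1_ts, sub_movie, hrf, grid_spec = grid,
                     model_kind = "mirror_vertical",
                     refine = config$fit$refine,
                     refine_maxit = config$fit$refine_maxit)
      )
    }
  }
  estimates <- do.call(rbind, est_rows)

  thresholded <- withCallingHandlers(
    apply_thresholds(estimates, config$stats$ve_min, config$stats$ecc_max),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  report <- list(
    config = config,
    package_version = as.character(utils::packageVersion("visurf")),
    n_estimates = nrow(estimates),
    n_thresholded = nrow(thresholded),
    warnings = warnings_seen
  )

  if (nrow(thresholded) > 0L) {
    report$medians <- median_summary(thresholded)
    report$median_tests <- median_difference_tests(
      report$medians, config$stats$alpha_corrected)
    report$trends <- group_trends(thresholded, config$stats$bin_deg,
                                  config$stats$n_boot_median, config$seed)
    report$distributions <- group_distributions(thresholded,
                                                config$stats$hist_bin)
  } else {
    report$medians <- report$median_tests <- report$trends <-
      report$distributions <- NULL
  }

  if (!is.null(patient_v1)) {
    report$model_comparison <- model_comparison_auc(
      patient_v1, config$stats$ve_min, config$stats$auc_n_boot,
      seed = config$seed + 99L)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_estimate_table(estimates, file.path(out_dir, "estimates.csv"))
    write_estimate_table(thresholded, file.path(out_dir, "estimates_thresholded.csv"))
    write_run_report(report_for_json(report), file.path(out_dir, "report.json"))
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  report$estimates <- estimates
  report
}

# Per-subject, per area group, per (condition, param) medians.
median_summary <- function(tb) {
  ag <- stats::aggregate(
    value ~ subject + group + area_group + condition + param,
    data = tb, FUN = stats::median)
  names(ag)[names(ag) == "value"] <- "median"
  tibble::as_tibble(ag[order(ag$param, ag$condition, ag$area_group,
                             ag$subject), ])
}

median_difference_tests <- function(med, alpha_corrected) {
  keys <- unique(med[, c("area_group", "condition", "param")])
  out <- list()
  for (k in seq_len(nrow(keys))) {
    sub <- merge(keys[k, ], med)
    pat <- sub$median[sub$group == "patient"]
    ctr <- sub$median[sub$group == "control"]
    if (length(pat) != 1L || length(ctr) < 2L) next
    tt <- case_vs_controls_median_test(pat, ctr, alpha_corrected)
    out[[length(out) + 1L]] <- tibble::tibble(
      area_group = keys$area_group[k], condition = keys$condition[k],
      param = keys$param[k], patient_median = pat,
      mean_control_median = mean(ctr), mean_diff = tt$mean_diff,
      t = tt$t, df = tt$df, p_value = tt$p_value,
      significant = tt$significant
    )
  }
  do.call(rbind, out)
}

# Patient-vs-pooled-controls size-eccentricity trends per (area_group,
# condition, size parameter), with the slope-difference F-test where both
# series have enough bins.
group_trends <- function(tb, bin_deg, n_boot, seed) {
  out <- list()
  for (param in intersect(c("prf_size", "cf_size"), unique(tb$param))) {
    for (cond in unique(tb$condition[tb$param == param])) {
      for (ag in stats::na.omit(unique(tb$area_group))) {
        sub <- tb[tb$param == param & tb$condition == cond &
                    tb$area_group %in% ag, ]
        pat <- sub[sub$group == "patient", ]
        ctr <- sub[sub$group == "control", ]
        if (nrow(pat) < 3L || nrow(ctr) < 3L) next
        bp <- binned_median_size(pat$ecc, pat$value, bin_deg,
                                 n_iter = n_boot, seed = seed)
        bc <- binned_median_size(ctr$ecc, ctr$value, bin_deg,
                                 n_iter = n_boot, seed = seed + 1L)
        if (nrow(bp) < 3L || nrow(bc) < 3L) next
        cmp <- compare_trends(bp, bc)
        out[[length(out) + 1L]] <- tibble::tibble(
          param = param, condition = cond, area_group = ag,
          slope_patient = cmp$slope_a, slope_controls = cmp$slope_b,
          delta_slope = cmp$delta_slope, f_statistic = cmp$f_statistic,
          p_value = cmp$p_value
        )
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

group_distributions <- function(tb, bin_width) {
  out <- list()
  keys <- unique(tb[, c("area_group", "condition", "param")])
  keys <- keys[!is.na(keys$area_group), ]
  for (k in seq_len(nrow(keys))) {
    sub <- merge(keys[k, ], tb)
    if (nrow(sub) == 0L) next
    top <- ceiling(max(sub$value) / bin_width) * bin_width
    pat <- sub$value[sub$group == "patient"]
    ctl <- split(sub$value[sub$group == "control"],
                 sub$subject[sub$group == "control"])
    ctl <- ctl[vapply(ctl, length, 1L) > 0]
    if (length(ctl) == 0L) next
    ctrl_hists <- lapply(ctl, relative_frequency, bin_width = bin_width,
                         max_value = top)
    out[[length(out) + 1L]] <- list(
      area_group = keys$area_group[k], condition = keys$condition[k],
      param = keys$param[k],
      patient = if (length(pat)) relative_frequency(pat, bin_width, top) else NULL,
      controls_mean = group_mean_distribution(ctrl_hists)
    )
  }
  out
}

# Pairwise model AUCs on the shared unit set where all three models reach
# the entry VE threshold; the more complex (bilateral) model is the test
# distribution, the unilateral model the baseline.
model_comparison_auc <- function(fits, ve_min, n_boot, seed) {
  ok <- fits$uni$ve >= ve_min & fits$mh$ve >= ve_min & fits$mv$ve >= ve_min
  if (sum(ok) < 3L) {
    return(list(n_units = sum(ok),
                note = "too few units pass the entry threshold"))
  }
  list(
    n_units = sum(ok),
    mirror_horizontal_vs_unilateral =
      auc_with_ci(fits$mh$ve[ok], fits$uni$ve[ok], n_boot, seed = seed),
    mirror_vertical_vs_unilateral =
      auc_with_ci(fits$mv$ve[ok], fits$uni$ve[ok], n_boot, seed = seed + 1L),
    mirror_vertical_vs_mirror_horizontal =
      auc_with_ci(fits$mv$ve[ok], fits$mh$ve[ok], n_boot, seed = seed + 2L)
  )
}

# Strip bulky curve objects for JSON serialisation.
report_for_json <- function(report) {
  if (!is.null(report$model_comparison)) {
    report$model_comparison <- lapply(report$model_comparison, function(x) {
      if (inherits(x, "auc_result")) {
        x$curve <- NULL
        unclass(x)
      } else x
    })
  }
  report$distributions <- NULL
  report$estimates <- NULL
  report
}
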