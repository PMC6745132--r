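#!/usr/bin/env Rscript
# Fit connective fields from V1 to each target area, for the active-state
# and resting-state runs of every subject.
#
# Exhaustive search over (V1 centre vertex x CF-size grid) of the Gaussian
# kernel over geodesic cortical distance; CF eccentricity is inherited from
# the fitted pRF eccentricity of the winning centre vertex. Writes
# results/cf_estimates.csv.

library(visurf)

cohort <- readRDS("scratch/cohort.rds")
dir.create("results", showWarnings = FALSE)

rows <- list()
for (sid in names(cohort$subjects)) {
  s <- cohort$subjects[[sid]]
  gt <- s$world$gt
  v1 <- sort(gt$vertex[gt$roi == "V1"])
  tgt_ids <- gt$vertex[gt$roi != "V1"]
  tgt_rois <- gt$roi[gt$roi != "V1"]
  prf_ecc <- setNames(s$prf$ecc, s$prf$vertex)[as.character(v1)]
  grp <- if (sid == "patient") "patient" else "control"

  for (cond in c("AS", "RS")) {
    run <- if (cond == "AS") s$as_run else s$rs_run
    cf <- fit_cf(run[as.character(tgt_ids), ], run[as.character(v1), ],
                 s$world$sheet, prf_ecc = prf_ecc, condition = cond)
    cf$target_roi <- tgt_rois
    rows[[paste(sid, cond)]] <- rbind(
      estimate_table(sid, grp, cf$unit, cf$target_roi, cond, "cf_ecc",
                     cf$ecc, cf$ecc, cf$ve),
      estimate_table(sid, grp, cf$unit, cf$target_roi, cond, "cf_size",
                     cf$sigma_mm, cf$ecc, cf$ve))
    cat(sprintf("%-9s CF_%s: median size %.1f mm, median VE %.2f\n",
                sid, cond, median(cf$sigma_mm), median(cf$ve)))
  }
}

write_estimate_table(do.call(rbind, rows), "results/cf_estimates.csv")
cat("CF estimates written to results/cf_estimates.csv\n")
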