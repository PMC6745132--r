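#!/usr/bin/env Rscript
# Fit unilateral 2D-Gaussian pRFs to every subject's active run.
#
# Grid search (15 x 15 centres, 8 log-spaced sizes) then Nelder-Mead
# refinement, amplitude constrained nonnegative. Writes one tidy estimate
# row per vertex to results/prf_estimates.csv.

library(visurf)

cohort <- readRDS("scratch/cohort.rds")
dir.create("results", showWarnings = FALSE)

grid <- prf_grid_spec(cohort$movie$field_radius_deg, 15L, 8L)
rows <- list()
for (sid in names(cohort$subjects)) {
  s <- cohort$subjects[[sid]]
  fit <- fit_prf(s$as_run, s$movie, cohort$hrf, grid_spec = grid,
                 refine_maxit = 40L)
  fit$vertex <- as.integer(rownames(s$as_run))
  fit$roi <- s$world$sheet$vertices$roi[
    match(fit$vertex, s$world$sheet$vertices$vertex)]
  grp <- if (sid == "patient") "patient" else "control"
  rows[[sid]] <- rbind(
    estimate_table(sid, grp, fit$vertex, fit$roi, "AS", "prf_ecc",
                   fit$ecc, fit$ecc, fit$ve),
    estimate_table(sid, grp, fit$vertex, fit$roi, "AS", "prf_size",
                   fit$sigma, fit$ecc, fit$ve))
  cat(sprintf("%-9s median VE %.2f, median ecc %.2f deg, median size %.2f deg\n",
              sid, median(fit$ve), median(fit$ecc), median(fit$sigma)))
  cohort$subjects[[sid]]$prf <- fit
}

saveRDS(cohort, "scratch/cohort.rds")
write_estimate_table(do.call(rbind, rows), "results/prf_estimates.csv")
cat("pRF estimates written to results/prf_estimates.csv\n")
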