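#!/usr/bin/env Rscript
# Case-versus-controls statistics on the fitted pRF and CF parameters.
#
# Thresholds estimates at VE >= 0.20 and eccentricity <= 10.2 deg, groups
# ROIs into early/late visual areas, then computes per-subject medians,
# patient-minus-control one-sample t-tests (Bonferroni alpha 0.0125),
# eccentricity-binned median sizes (1-deg bins, 1000-draw bootstrap CIs)
# with patient-vs-controls slope-difference F-tests, and 0.5-unit relative
# frequency distributions.

library(visurf)

est <- rbind(read_estimate_table("results/prf_estimates.csv"),
             read_estimate_table("results/cf_estimates.csv"))
kept <- apply_thresholds(est)
cat(sprintf("thresholding: %d of %d estimates kept\n", nrow(kept), nrow(est)))

## per-subject medians and patient-minus-control tests
meds <- aggregate(value ~ subject + group + area_group + condition + param,
                  data = kept, FUN = median)
names(meds)[names(meds) == "value"] <- "median"
write.csv(meds, "results/medians.csv", row.names = FALSE)

tests <- list()
keys <- unique(meds[, c("area_group", "condition", "param")])
for (k in seq_len(nrow(keys))) {
  sub <- merge(keys[k, ], meds)
  pat <- sub$median[sub$group == "patient"]
  ctr <- sub$median[sub$group == "control"]
  if (length(pat) != 1L || length(ctr) < 2L) next
  tt <- case_vs_controls_median_test(pat, ctr)
  tests[[k]] <- cbind(keys[k, ], patient = pat, controls_mean = mean(ctr),
                      mean_diff = tt$mean_diff, t = tt$t, df = tt$df,
                      p = tt$p_value, significant = tt$significant)
}
tests <- do.call(rbind, tests)
print(tests, digits = 3)
write.csv(tests, "results/median_tests.csv", row.names = FALSE)

## size-eccentricity trends (CF size, both conditions, early areas)
trends <- list()
for (cond in c("AS", "RS")) {
  sub <- kept[kept$param == "cf_size" & kept$condition == cond &
                kept$area_group == "early", ]
  pat <- sub[sub$group == "patient", ]
  ctr <- sub[sub$group == "control", ]
  if (nrow(pat) < 3L || nrow(ctr) < 3L) next
  bp <- binned_median_size(pat$ecc, pat$value, seed = 1L)
  bc <- binned_median_size(ctr$ecc, ctr$value, seed = 2L)
  if (nrow(bp) < 3L || nrow(bc) < 3L) next
  cmp <- compare_trends(bp, bc)
  trends[[cond]] <- data.frame(
    condition = cond, slope_patient = cmp$slope_a,
    slope_controls = cmp$slope_b, delta_slope = cmp$delta_slope,
    F = cmp$f_statistic, p = cmp$p_value)
}
trends <- do.call(rbind, trends)
print(trends, digits = 3)
write.csv(trends, "results/cf_size_trends.csv", row.names = FALSE)

## relative frequency distributions of CF size (resting state, early areas)
sub <- kept[kept$param == "cf_size" & kept$condition == "RS" &
              kept$area_group == "early", ]
top <- ceiling(max(sub$value) / 0.5) * 0.5
pat_hist <- relative_frequency(sub$value[sub$group == "patient"], 0.5, top)
ctl <- split(sub$value[sub$group == "control"],
             sub$subject[sub$group == "control"])
ctl_mean <- group_mean_distribution(
  lapply(ctl, relative_frequency, bin_width = 0.5, max_value = top))
dist <- data.frame(bin_lo = pat_hist$bin_lo, bin_hi = pat_hist$bin_hi,
                   patient = pat_hist$freq, controls_mean = ctl_mean$mean_freq,
                   controls_ci_lo = ctl_mean$ci_lo,
                   controls_ci_hi = ctl_mean$ci_hi)
write.csv(dist, "results/cf_rs_size_distribution.csv", row.names = FALSE)
cat(sprintf("patient mass above 9 mm: %.2f; controls: %.2f\n",
            sum(dist$patient[dist$bin_lo >= 9]),
            sum(dist$controls_mean[dist$bin_lo >= 9])))
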