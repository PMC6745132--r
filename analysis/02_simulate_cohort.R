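#!/usr/bin/env Rscript
# Simulate the study cohort: one hemianopic "patient" and three controls.
#
# Every subject is a one-hemisphere cortical sheet (V1 plus two target areas)
# with known pRF and CF parameters. The patient sees only the left hemifield
# (hemifield-masked stimulus) and carries enlarged true connective fields
# (2x the control 3-mm kernels) — the synthetic analogue of the enlarged
# resting-state CFs this analysis is designed to detect. Controls see the
# full field. Active runs add AR(1) noise at 0.2 x the mean signal SD.

library(visurf)

dir.create("scratch", showWarnings = FALSE)
seed <- 7L

movie <- build_sweep_sequence(grid_n = 61L)
hrf <- double_gamma_hrf(movie$frame_duration_s)

subjects <- c("patient", paste0("control", 1:3))
cohort <- list(movie = movie, hrf = hrf, seed = seed, subjects = list())

for (i in seq_along(subjects)) {
  sid <- subjects[i]
  is_patient <- sid == "patient"
  world <- make_visual_cortex_sheet(
    n_v1_vertices = 64L, vertices_per_target_area = 25L,
    target_areas = c("V2", "V3A"), area_size_factor = c(1.5, 2.5),
    cf_sigma_mm = if (is_patient) 6 else 3,
    seed = seed * 1000L + i)
  sub_movie <- if (is_patient) mask_hemifield(movie, "left") else movie
  sig <- signal_sd(world$sheet, world$gt, sub_movie, hrf)
  as_run <- simulate_active_run(world$sheet, world$gt, sub_movie, hrf,
                                noise_spec(0.2 * sig, seed = seed * 1000L + i + 100L))
  rs_run <- simulate_resting_run(world$sheet, world$gt, 120, 5,
                                 noise_spec(0.2, seed = seed * 1000L + i + 200L))
  cohort$subjects[[sid]] <- list(world = world, movie = sub_movie,
                                 as_run = as_run, rs_run = rs_run)
  cat(sprintf("%-9s %3d vertices, signal SD %.3f, active %dx%d, resting %dx%d\n",
              sid, nrow(world$sheet$vertices), sig,
              nrow(as_run), ncol(as_run), nrow(rs_run), ncol(rs_run)))
}

saveRDS(cohort, "scratch/cohort.rds")
cat("cohort written to scratch/cohort.rds\n")
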