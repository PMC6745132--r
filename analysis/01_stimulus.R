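#!/usr/bin/env Rscript
# Build the drifting-bar aperture movie and check its timing bookkeeping.
#
# The canonical cycle: 192 s of eight bar sweeps (1.5-s motion steps, control
# geometry: 10.21-deg radius, 2.75-deg bar), with the final 12 s of each
# diagonal sweep replaced by mean-luminance blanks. A 204-s scan at TR 1.5 s
# gives 136 volumes, 128 analyzed after the 12-s prescan; 198-s scans miss
# the last 4 (blank) frames of the cycle.

library(visurf)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

movie <- build_sweep_sequence()
print(movie)

blank <- apply(movie$frames, 3L, sum) == 0
runs <- rle(blank)
cat(sprintf("blank frames: %d (%.0f s in %d disjoint periods)\n",
            sum(blank), sum(blank) * movie$frame_duration_s,
            sum(runs$values)))

timing_full <- scan_timing(204, 1.5, 12)
timing_short <- scan_timing(198, 1.5, 12)
summary <- data.frame(
  scan = c("full_204s", "short_198s"),
  n_volumes = c(timing_full$n_volumes, timing_short$n_volumes),
  n_analyzed = c(timing_full$n_analyzed, timing_short$n_analyzed),
  n_missing_end_frames = c(timing_full$n_missing_end_frames,
                           timing_short$n_missing_end_frames)
)
print(summary)
write.csv(summary, "results/scan_timing.csv", row.names = FALSE)

# the short-scan movie used when predictions must match 124 recorded volumes
short_movie <- truncate_for_short_scan(movie, timing_short$n_missing_end_frames)
cat(sprintf("truncated movie: %d frames (all dropped frames blank: %s)\n",
            n_frames(short_movie),
            all(movie$frames[, , (n_frames(short_movie) + 1):n_frames(movie)] == 0)))

write_aperture_nifti(movie, "scratch/aperture_movie.nii.gz")
cat("aperture movie written to scratch/aperture_movie.nii.gz\n")
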