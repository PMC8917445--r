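#!/usr/bin/env Rscript
# Stage 2: validate the imaging stage end to end -- render a 1x5 fast-start
# batch to frames, run the tracker, and compare the recovered centroids
# with the generator's ground truth.

suppressPackageStartupMessages({library(swimkin); library(dplyr)})
seed <- 20220120
dir.create("results", showWarnings = FALSE)

sim <- simulate_fast_start_trials(fast_start_sim_params(
  n_fish = 5, trials_per_fish = 1, trial_retention = 1,
  seed = derive_seed(seed, "video")))
layout <- dish_layout("1x5", px_per_mm = 4)
cat(sprintf("rendering %d frames of a 1x5 dish array (%d x %d px, %.0f px/mm)\n",
            length(unique(sim$tracks$frame)), attr(layout, "img_rows"),
            attr(layout, "img_cols"), calibrate_scale(layout)))

ren <- render_frames(sim$tracks, layout,
                     render_params(pixel_noise_sd = 0.05 * (0.85 - 0.25),
                                   seed = derive_seed(seed, "noise")))
trk <- track_frames(ren$frames, layout, frame_rate = sim$params$frame_rate,
                    min_area_px = 10)
write_tracks(trk, "results/tracked_1x5.csv")

m <- inner_join(trk, sim$tracks, by = c("fish_id", "frame"), suffix = c("", "_true"))
rmse_px <- sqrt(mean(((m$x_mm - m$x_mm_true)^2 + (m$y_mm - m$y_mm_true)^2)[m$valid]) ) * 4
cat(sprintf("tracker vs truth: %.1f%% frames valid, centroid RMSE %.2f px\n",
            100 * mean(trk$valid), rmse_px))
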