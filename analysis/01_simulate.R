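#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- fast-start trials at study scale,
# feeding sessions across ages and treatments, and the offspring cohort --
# and write the raw tables that the later stages consume.

suppressPackageStartupMessages(library(swimkin))
seed <- 20220120
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

## fast-start experiment: 207 newborns, up to 3 startle trials each
sim <- simulate_fast_start_trials(fast_start_sim_params(seed = seed))
cat(sprintf("fast-start experiment: %d trials from %d fish, %.0f%% latent responders\n",
            nrow(sim$trials), length(unique(sim$trials$fish_id)),
            100 * mean(sim$trials$responder)))
write_tracks(sim$tracks, "results/data/faststart_tracks.csv")
utils::write.csv(sim$trials, "results/data/faststart_truth.csv", row.names = FALSE)
utils::write.csv(sim$speeds, "results/data/faststart_speeds.csv", row.names = FALSE)

## feeding sessions: 6 fish x 3 ages, alternating treatments
sessions <- list()
for (f in 1:6) for (a in c(0, 2, 7)) {
  trt <- ifelse(f %% 2 == 0, "HF", "LF")
  fs <- simulate_feeding_session(
    feeding_sim_params(treatment = trt, age_days = a,
                       experimental_day = 5 + 7 * f,
                       seed = derive_seed(seed, "feed", f, a)),
    fish_id = f)
  sessions[[length(sessions) + 1]] <- fs
  write_events(fs$events, sprintf("results/data/feeding_events_f%d_a%d.csv", f, a))
  write_tracks(fs$track, sprintf("results/data/feeding_track_f%d_a%d.csv", f, a))
}
cat(sprintf("feeding sessions: %d (6 fish x 3 ages), %d frames each\n",
            length(sessions), nrow(sessions[[1]]$profile)))

## offspring cohort: 50 mothers, LF/HF split, days 1-51
co <- simulate_cohort(cohort_sim_params(seed = derive_seed(seed, "cohort")))
cat(sprintf("cohort: %d offspring from %d mothers (LF slope %.3f, HF slope %.3f mg/day by construction)\n",
            nrow(co$records), co$params$n_mothers,
            co$params$beta$dry_mass[["day"]],
            co$params$beta$dry_mass[["day"]] + co$params$beta$dry_mass[["treatment_day"]]))
utils::write.csv(co$records, "results/data/cohort_records.csv", row.names = FALSE)
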