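test_that("fast-start generator is deterministic and validates its inputs", {
  p <- fast_start_sim_params(n_fish = 4, trials_per_fish = 2, trial_retention = 1,
                             seed = 9)
  s1 <- simulate_fast_start_trials(p)
  s2 <- simulate_fast_start_trials(p)
  expect_identical(s1, s2)
  # different seed, different draws
  s3 <- simulate_fast_start_trials(fast_start_sim_params(
    n_fish = 4, trials_per_fish = 2, trial_retention = 1, seed = 10))
  expect_false(identical(s1$trials$true_peak_speed, s3$trials$true_peak_speed))

  expect_error(fast_start_sim_params(responder_fraction = 1.2), "probability")
  expect_error(fast_start_sim_params(duration = 0.1), "0.157")
  expect_error(fast_start_sim_params(responder_peak_speed = list(mean = 10, sd = 1)),
               "exceed")
  expect_error(fast_start_sim_params(latency = list(m = 1)), "mean")
})

test_that("degenerate peak-speed distribution gives exactly the stated peak", {
  p <- fast_start_sim_params(n_fish = 5, trials_per_fish = 1, trial_retention = 1,
                             responder_fraction = 1,
                             responder_peak_speed = list(mean = 200, sd = 0),
                             speed_jitter = 0, seed = 1)
  sim <- simulate_fast_start_trials(p)
  expect_true(all(sim$trials$responder))
  expect_equal(sim$trials$true_peak_speed, rep(200, 5))
  # the sampled speed profile peaks at (essentially) the true peak
  peaks <- tapply(sim$speeds$v_true, sim$speeds$trial_id, max)
  expect_true(all(peaks <= 200 + 1e-9 & peaks > 199))
})

test_that("study-scale defaults give ~270 trials with ~1/3 responders", {
  sim <- simulate_fast_start_trials(fast_start_sim_params(seed = 3))
  n <- nrow(sim$trials)
  expect_gt(n, 270 - 3 * sqrt(621 * 0.435 * 0.565))
  expect_lt(n, 270 + 3 * sqrt(621 * 0.435 * 0.565))
  frac <- mean(sim$trials$responder)
  expect_gt(frac, 0.33 - 3 * sqrt(0.33 * 0.67 / 270))
  expect_lt(frac, 0.33 + 3 * sqrt(0.33 * 0.67 / 270))
})

test_that("speed integral equals the emitted path length and stays in the dish", {
  sim <- small_faststart_sim(seed = 5)
  dt <- 1 / sim$params$frame_rate
  for (id in sim$trials$trial_id) {
    tr <- sim$tracks[sim$tracks$trial_id == id, ]
    v <- sim$speeds$v_true[sim$speeds$trial_id == id]
    path <- sum(sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2))
    expect_equal(path, sum(v[-length(v)]) * dt, tolerance = 1e-3)
    expect_true(all(sqrt(tr$x_mm^2 + tr$y_mm^2) <=
                      sim$params$dish_diameter_mm / 2 - 4 + 1e-9))
  }
})

test_that("feeding generator: rates, segment truth, and arrival counts", {
  expect_error(feeding_sim_params(bout_rate_feeding = -1), "non-negative")

  # no control bouts -> true control mean speed is zero
  quiet <- simulate_feeding_session(feeding_sim_params(
    bout_rate_control = 0, control_duration = 60, feeding_duration = 60,
    supply_gap = 5, seed = 2))
  expect_equal(quiet$truth$true_mean_speed[quiet$truth$segment == "control"], 0)

  # ontogenetic ordering is built into the defaults: HF age 7 beats age 0
  s0 <- simulate_feeding_session(feeding_sim_params(treatment = "HF", age_days = 0,
                                                    seed = 4))
  s7 <- simulate_feeding_session(feeding_sim_params(treatment = "HF", age_days = 7,
                                                    seed = 4))
  expect_gt(s7$truth$true_mean_speed[s7$truth$segment == "feeding"],
            s0$truth$true_mean_speed[s0$truth$segment == "feeding"])

  # Poisson arrival counts: within 3*sqrt(300r) of 300r in >= 95% of seeds
  rate <- 0.25
  ok <- 0
  for (s in 1:60) {
    fs <- simulate_feeding_session(feeding_sim_params(
      bout_rate_feeding = rate, bout_rate_control = 0, supply_gap = 1, seed = s))
    n_b <- sum(fs$bouts$segment == "feeding")
    if (abs(n_b - 300 * rate) <= 3 * sqrt(300 * rate)) ok <- ok + 1
  }
  expect_gte(ok / 60, 0.95)
})

test_that("cohort generator: exact surface at zero variance, structural invariants", {
  p0 <- cohort_sim_params(n_mothers = 10, offspring_per_mother = 4,
                          sigma_mother = c(dry_mass = 0, sqrt_body_fat = 0),
                          sigma_resid = c(dry_mass = 0, sqrt_body_fat = 0),
                          seed = 6)
  co <- simulate_cohort(p0)
  b <- p0$beta$dry_mass
  r <- co$records
  trt <- as.integer(r$treatment == "HF")
  expected <- b[["intercept"]] + b[["treatment"]] * trt + b[["day"]] * r$experimental_day +
    b[["day2"]] * r$experimental_day^2 + b[["age"]] * r$age_days +
    b[["treatment_day"]] * trt * r$experimental_day +
    b[["treatment_age"]] * trt * r$age_days
  expect_equal(r$dry_mass, expected, tolerance = 1e-12)
  expect_true(all(r$lean_mass <= r$dry_mass + 1e-12))
  expect_true(all(r$body_fat >= 0))
  expect_equal(r$body_fat, r$dry_mass - r$lean_mass, tolerance = 1e-12)

  # between-mother variance of mother means tracks sigma_mother^2
  pv <- cohort_sim_params(n_mothers = 200, offspring_per_mother = 12,
                          sigma_resid = c(dry_mass = 0, sqrt_body_fat = 0),
                          seed = 8)
  cv <- simulate_cohort(pv)
  # remove the fixed-effect surface first, then compare mother-mean variance
  bd <- pv$beta$dry_mass
  trt <- as.integer(cv$records$treatment == "HF")
  resid <- cv$records$dry_mass -
    (bd[["intercept"]] + bd[["treatment"]] * trt + bd[["day"]] * cv$records$experimental_day +
       bd[["age"]] * cv$records$age_days +
       bd[["treatment_day"]] * trt * cv$records$experimental_day +
       bd[["treatment_age"]] * trt * cv$records$age_days)
  v_emp <- var(tapply(resid, cv$records$mother_id, mean))
  expect_lt(abs(v_emp - pv$sigma_mother[["dry_mass"]]^2),
            0.2 * pv$sigma_mother[["dry_mass"]]^2)

  # alive probability declines with experimental day
  big <- simulate_cohort(cohort_sim_params(n_mothers = 100, seed = 12))
  early <- big$records$experimental_day <= 17
  late <- big$records$experimental_day >= 35
  expect_gt(mean(big$records$alive[early]), mean(big$records$alive[late]))
})

test_that("renderer: stationary fish, composite layouts, ground-truth centroids", {
  still <- tibble::tibble(fish_id = 1L, frame = 0:14, time_s = (0:14) / 100,
                          x_mm = 2, y_mm = -1)
  lay <- dish_layout("1x5", px_per_mm = 4)
  ren <- render_frames(still, lay[1, ], render_params(pixel_noise_sd = 0, seed = 1))
  expect_true(all(vapply(ren$frames[-1], identical, logical(1), ren$frames[[1]])))
  # rasterised silhouette centroid vs analytic centre, sub-half-pixel
  img <- ren$frames[[1]]
  fish <- which(img < 0.5, arr.ind = TRUE)
  expect_lt(abs(mean(fish[, 1] - 1) - ren$truth$row_px[1]), 0.5)
  expect_lt(abs(mean(fish[, 2] - 1) - ren$truth$col_px[1]), 0.5)

  # composite arrays match the two filming set-ups
  sim9 <- simulate_fast_start_trials(fast_start_sim_params(
    n_fish = 9, trials_per_fish = 1, trial_retention = 1, duration = 0.16,
    acclimation_s = 0, seed = 2))
  lay9 <- dish_layout("3x3", dish_diameter_mm = 35, px_per_mm = 3)
  ren9 <- render_frames(sim9$tracks, lay9, render_params(seed = 3))
  expect_equal(length(unique(ren9$truth$dish_id)), 9)
  sim5 <- simulate_fast_start_trials(fast_start_sim_params(
    n_fish = 5, trials_per_fish = 1, trial_retention = 1, duration = 0.16,
    acclimation_s = 0, seed = 2))
  ren5 <- render_frames(sim5$tracks, dish_layout("1x5", px_per_mm = 3),
                        render_params(seed = 3))
  expect_equal(length(unique(ren5$truth$dish_id)), 5)

  # a track leaving the dish is rejected with the frame index
  out <- tibble::tibble(fish_id = 1L, frame = 0:1, time_s = c(0, 0.01),
                        x_mm = c(0, 30), y_mm = 0)
  expect_error(render_frames(out, lay[1, ], render_params()), "frame 1")
})

test_that("rasterised ellipse centroid is within 0.5 px of the analytic centre", {
  set.seed(33)
  lay <- dish_layout("1x5", px_per_mm = 4)[1, ]
  for (i in 1:10) {
    x <- runif(1, -5, 5); y <- runif(1, -5, 5)
    tr <- tibble::tibble(fish_id = 1L, frame = 0:1, time_s = c(0, 0.01),
                         x_mm = c(x, x + runif(1, -0.2, 0.2)),
                         y_mm = c(y, y + runif(1, -0.2, 0.2)))
    ren <- render_frames(tr, lay, render_params(pixel_noise_sd = 0, seed = i))
    img <- ren$frames[[1]]
    fish <- which(img < 0.5, arr.ind = TRUE)
    expect_gte(nrow(fish), 10) # >= 10 px long
    expect_lt(abs(mean(fish[, 1] - 1) - ren$truth$row_px[1]), 0.5)
    expect_lt(abs(mean(fish[, 2] - 1) - ren$truth$col_px[1]), 0.5)
  }
})
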