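test_that("polynomial motion is differentiated exactly", {
  dt <- 0.017 / 6
  t <- seq(0, 0.5, by = dt)
  lin <- tibble::tibble(frame = seq_along(t) - 1L, time_s = t,
                        x_mm = 30 * t, y_mm = 0 * t)
  sm <- smooth_track(lin, window = 7, order = 2)
  expect_equal(sm$dx, rep(30, length(t)), tolerance = 1e-9)
  expect_equal(sm$dy, rep(0, length(t)), tolerance = 1e-9)

  quad <- tibble::tibble(frame = seq_along(t) - 1L, time_s = t,
                         x_mm = 5 * t^2, y_mm = 2 * t - t^2)
  smq <- smooth_track(quad, window = 7, order = 2)
  expect_equal(smq$ddx, rep(10, length(t)), tolerance = 1e-6)
  expect_equal(smq$ddy, rep(-2, length(t)), tolerance = 1e-6)

  expect_error(smooth_track(lin, window = 6), "window")
  expect_error(smooth_track(lin, window = 7, order = 7), "order")
})

test_that("uniform circular motion gives v = R*omega and a = R*omega^2 across frame rates", {
  for (dt in c(1 / 200, 1 / 353, 1 / 500)) {
    tr <- circle_track(R = 10, omega = 2, dt = dt)
    pr <- compute_speed_profile(tr)
    interior <- pr$valid & !pr$edge
    expect_lt(max(abs(pr$v[interior] - 20) / 20), 0.02)
    expect_lt(max(abs(pr$a[interior] - 40) / 40), 0.05)
  }
})

test_that("stationary tracks give zero speed and acceleration", {
  t <- seq(0, 0.2, by = 0.005)
  tr <- tibble::tibble(frame = seq_along(t) - 1L, time_s = t, x_mm = 3, y_mm = -2)
  pr <- compute_speed_profile(tr)
  expect_equal(pr$v, rep(0, length(t)), tolerance = 1e-9)
  expect_equal(pr$a, rep(0, length(t)), tolerance = 1e-9)
})

test_that("smoothing reduces speed noise at least 3x versus finite differences", {
  set.seed(2)
  dt <- 0.017 / 6
  t <- seq(0, 1, by = dt)
  x <- 30 * t + rnorm(length(t), 0, 0.1)
  y <- rnorm(length(t), 0, 0.1)
  tr <- tibble::tibble(frame = seq_along(t) - 1L, time_s = t, x_mm = x, y_mm = y)
  pr <- compute_speed_profile(tr, window = 7, order = 2)
  ok <- pr$valid & !pr$edge
  rmse_sg <- sqrt(mean((pr$v[ok] - 30)^2))
  rmse_fd <- sqrt(mean((sqrt(diff(x)^2 + diff(y)^2) / dt - 30)^2))
  expect_gt(rmse_fd / rmse_sg, 3)
})

test_that("runs shorter than the window are invalidated with a warning", {
  t <- seq(0, 0.1, by = 0.005)
  tr <- tibble::tibble(frame = seq_along(t) - 1L, time_s = t,
                       x_mm = t * 10, y_mm = 0,
                       valid = rep(c(TRUE, FALSE), c(5, length(t) - 5)))
  tr$valid[10:21] <- TRUE
  expect_warning(sm <- smooth_track(tr, window = 7), "invalidated")
  expect_false(any(sm$valid[1:5]))
  expect_true(all(sm$valid[10:21]))
})

test_that("speed profiles of simulated trials integrate to path length and hit true peaks", {
  sim <- simulate_fast_start_trials(fast_start_sim_params(
    n_fish = 8, trials_per_fish = 1, trial_retention = 1, responder_fraction = 1,
    speed_jitter = 0, acclimation_s = 0.1, seed = 21))
  dt <- 1 / sim$params$frame_rate
  # wall reflections kink the path; the local-polynomial fit legitimately
  # cuts such corners, so the integral identity is asserted on smooth trials
  smooth_ids <- sim$trials$trial_id[sim$trials$n_reflections == 0]
  expect_gte(length(smooth_ids), 3)
  for (id in smooth_ids) {
    tr <- sim$tracks[sim$tracks$trial_id == id, ]
    pr <- compute_speed_profile(tr)
    # integral of the estimated speed ~ path length (1%)
    path <- sum(sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2))
    integral <- sum(pr$v[-nrow(pr)] * dt)
    expect_lt(abs(integral - path) / path, 0.01)
    # profile maximum within 5% of the generator's true peak speed
    truep <- sim$trials$true_peak_speed[sim$trials$trial_id == id]
    expect_lt(abs(max(pr$v, na.rm = TRUE) - truep) / truep, 0.05)
  }
})

test_that("robust extremum follows the stated quantile convention", {
  expect_equal(robust_extremum(1:100, 0.95), 98)
  expect_equal(robust_extremum(rep(7, 50)), 7) # fallback branch
  expect_error(robust_extremum(numeric(0)), "finite")

  # agreement with the brute-force sort/threshold/average oracle
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:200, 1)
    x <- switch(sample(3, 1),
                rnorm(n, 50, 20),
                rexp(n, 0.1),
                runif(n, 0, 300))
    q <- sample(c(0.5, 0.9, 0.95, 0.99), 1)
    expect_identical(robust_extremum(x, q), robust_extremum_oracle(x, q))
  }
})

test_that("kinematic summaries: definitions and ground-truth agreement", {
  t <- seq(0, 1, by = 0.01)
  const <- tibble::tibble(frame = seq_along(t) - 1L, time_s = t,
                          v = rep(12, length(t)), a = rep(0, length(t)),
                          valid = TRUE)
  s <- summarize_kinematics(const, segment = "control")
  expect_equal(s$v_mean, 12)
  expect_equal(s$v_max, 12)

  # a single spike in a non-degenerate profile: the quantile-mean maximum
  # averages the spike with the rest of the upper tail, so it sits strictly
  # below the raw spike
  set.seed(8)
  spike <- tibble::tibble(frame = 0:199, time_s = (0:199) / 100,
                          v = runif(200, 10, 20), a = NA_real_, valid = TRUE)
  spike$v[50] <- 500
  s2 <- summarize_kinematics(spike)
  expect_lt(s2$v_max, 500)
  expect_gt(s2$v_max, s2$v_mean)

  expect_error(summarize_kinematics(const, frames = 5000, segment = "feeding"),
               "feeding")

  # v_max >= v_mean on random profiles
  set.seed(3)
  for (i in 1:20) {
    pr <- tibble::tibble(frame = 0:199, time_s = (0:199) / 100,
                         v = rexp(200, 0.05), a = NA_real_, valid = TRUE)
    s <- summarize_kinematics(pr)
    expect_gte(s$v_max, s$v_mean)
  }

  # synthetic feeding segment mean within 3% of generator truth
  fs <- simulate_feeding_session(feeding_sim_params(treatment = "LF", age_days = 2,
                                                    seed = 14))
  sp <- split_session(fs$profile, fs$events)
  sm <- summarize_session(sp, list(fish_id = 1, age_days = 2, treatment = "LF",
                                   experimental_day = 20))
  for (seg in c("control", "feeding")) {
    truth <- fs$truth$true_mean_speed[fs$truth$segment == seg]
    expect_lt(abs(sm$v_mean[sm$period == seg] - truth), 0.03 * max(truth, 1))
  }
})
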