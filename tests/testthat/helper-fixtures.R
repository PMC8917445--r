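# shared fixtures, all generated in code

# uniform circular motion: R mm radius, omega rad/s -> v = R*omega, a = R*omega^2
circle_track <- function(R = 10, omega = 2, dt = 1 / 353, duration = 2) {
  t <- seq(0, duration, by = dt)
  tibble::tibble(frame = seq_along(t) - 1L, time_s = t,
                 x_mm = R * cos(omega * t), y_mm = R * sin(omega * t))
}

# small, fast fast-start simulation (well-separated modes)
small_faststart_sim <- function(seed = 42, n_fish = 12, responder_fraction = 0.33) {
  simulate_fast_start_trials(fast_start_sim_params(
    n_fish = n_fish, trials_per_fish = 1, trial_retention = 1,
    responder_fraction = responder_fraction, seed = seed))
}

# brute-force oracle for the quantile-mean robust maximum:
# sort, threshold at the type-7 quantile, average what lies strictly above
robust_extremum_oracle <- function(x, q = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  qv <- x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  above <- x[x > qv]
  if (length(above) == 0) max(x) else mean(above)
}

# draw a two-Gaussian mixture whose density valley is 50-80% deep relative
# to the smaller mode (the regime where the valley is statistically
# localisable); returns samples plus the analytic valley location
localisable_mixture <- function(seed, n = 6000) {
  set.seed(seed)
  repeat {
    mu1 <- runif(1, 15, 30); sd1 <- runif(1, 6, 10)
    mu2 <- runif(1, 80, 120); sd2 <- runif(1, 18, 30)
    w1 <- runif(1, 0.5, 0.7)
    dens <- function(x) w1 * dnorm(x, mu1, sd1) + (1 - w1) * dnorm(x, mu2, sd2)
    opt <- optimize(dens, c(mu1, mu2))
    peak_small <- min(dens(mu1), dens(mu2))
    depth <- 1 - opt$objective / peak_small
    if (depth >= 0.5 && depth <= 0.8) break
  }
  x <- c(rnorm(round(n * w1), mu1, sd1), rnorm(n - round(n * w1), mu2, sd2))
  list(speeds = x[x > 0], valley = opt$minimum, depth = depth)
}

# shift tracked timestamps so the stimulus sits at t = 0
stimulus_align <- function(track, acclimation_s, frame_rate) {
  track$time_s <- track$time_s - ceiling(acclimation_s * frame_rate) / frame_rate
  track
}
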