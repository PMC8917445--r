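test_that("response window extraction matches the frame arithmetic", {
  dt <- 0.017 / 6
  t <- (-35:70) * dt # stimulus-aligned grid: t = 0 is a frame
  prof <- tibble::tibble(frame = seq_along(t) - 1L, time_s = t, v = 1, valid = TRUE)
  w <- extract_response_window(prof)
  # floor(0.157 / dt) + 1 = 56 frames at the default frame interval
  expect_equal(nrow(w), 56)
  expect_gte(min(w$time_s), -1e-9)
  expect_lte(max(w$time_s), 0.157 + 1e-9)

  # degenerate [0, 0] window: the single stimulus frame
  w0 <- extract_response_window(prof, c(0, 0))
  expect_equal(nrow(w0), 1)
  expect_equal(w0$time_s, 0)

  short <- prof[prof$time_s < 0.1, ]
  expect_error(extract_response_window(short), "0.157")
})

test_that("mean speed curve averages trials and breaks peak ties to the earliest frame", {
  t <- seq(0, 0.15, by = 0.01)
  one <- tibble::tibble(trial_id = 1L, frame = seq_along(t) - 1L, time_s = t,
                        v = sin(t * 20) + 1, valid = TRUE)
  two <- one
  two$trial_id <- 2L
  mc <- mean_speed_curve(dplyr::bind_rows(one, two))
  expect_equal(mc$curve$mean_speed, one$v) # identical profiles: mean equals either
  expect_error(mean_speed_curve(one), "2 trials")

  flat <- dplyr::bind_rows(one, two)
  flat$v <- 5
  expect_equal(mean_speed_curve(flat)$peak_frame, 0L) # tie -> earliest
})

test_that("valley threshold: empty gap, localisable mixtures, unimodal fallback", {
  # two disjoint uniform blocks -> threshold inside the empty gap
  set.seed(4)
  th <- estimate_response_threshold(c(runif(500, 0, 40), runif(500, 120, 200)))
  expect_false(th$fallback)
  expect_gt(th$threshold, 40)
  expect_lt(th$threshold, 120)

  # two-Gaussian mixtures with a 50-80% deep valley: estimate within
  # 2 bin widths of the analytic density minimum in >= 95/100 seeds
  ok <- 0
  for (s in 1:100) {
    mx <- localisable_mixture(s)
    t <- suppressWarnings(estimate_response_threshold(mx$speeds))
    if (!t$fallback && abs(t$threshold - mx$valley) <= 2 * t$bin_width) ok <- ok + 1
  }
  expect_gte(ok, 95)

  # unimodal input falls back to the configured 60 mm/s default
  set.seed(6)
  expect_warning(thu <- estimate_response_threshold(rnorm(2000, 100, 20)),
                 "not bimodal")
  expect_true(thu$fallback)
  expect_equal(thu$threshold, 60)

  expect_error(estimate_response_threshold(numeric(0)), "no speeds")

  # structural invariant: low peak < valley < high peak (in speed)
  expect_true(th$peak_bins[1] < th$valley_bin && th$valley_bin < th$peak_bins[2])
})

test_that("7-frame window rule: strict threshold, all three rules, clipping", {
  prof <- tibble::tibble(frame = 0:55, time_s = (0:55) * 0.017 / 6,
                         v = rep(59, 56), valid = TRUE)
  # all frames at 59 vs threshold 60: no response under any rule
  for (rule in c("mean", "any", "all")) {
    expect_false(classify_response(prof, 60, peak_frame = 28, rule = rule)$response)
  }
  # boundary: exactly at the threshold is NOT a response (strict inequality)
  prof60 <- prof; prof60$v[] <- 60
  expect_false(classify_response(prof60, 60, peak_frame = 28)$response)
  prof61 <- prof; prof61$v[] <- 61
  for (rule in c("mean", "any", "all")) {
    expect_true(classify_response(prof61, 60, peak_frame = 28, rule = rule)$response)
  }
  # window clipped at the interval edge is flagged
  cl <- classify_response(prof61, 60, peak_frame = 1)
  expect_true(cl$clipped)
  expect_true(cl$response)
  # no valid frames -> unclassifiable
  profNA <- prof; profNA$valid <- FALSE
  expect_true(classify_response(profNA, 60, peak_frame = 28)$unclassifiable)
})

test_that("disjoint mixtures are classified without error against latent truth", {
  sim <- small_faststart_sim(seed = 31, n_fish = 40)
  prof <- true_speed_profiles(sim)
  cl <- classify_trials(prof, 60)
  cmp <- dplyr::inner_join(cl, sim$trials[, c("trial_id", "responder")],
                           by = "trial_id")
  expect_equal(cmp$response, cmp$responder)
})

test_that("rule ordering and threshold monotonicity hold on generated data", {
  sim <- small_faststart_sim(seed = 17, n_fish = 30)
  prof <- true_speed_profiles(sim)
  for (thr in c(30, 60, 100)) {
    r_all <- classify_trials(prof, thr, rule = "all")
    r_mean <- classify_trials(prof, thr, rule = "mean")
    r_any <- classify_trials(prof, thr, rule = "any")
    # responses(all) subset of responses(mean) subset of responses(any)
    expect_true(all(!r_all$response | r_mean$response))
    expect_true(all(!r_mean$response | r_any$response))
  }
  for (rule in c("mean", "any", "all")) {
    counts <- vapply(c(0, 20, 40, 60, 80, 120, 200, Inf), function(thr) {
      sum(classify_trials(prof, thr, rule = rule)$response)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("sensitivity sweep covers the threshold x rule cross with sane extremes", {
  sim <- small_faststart_sim(seed = 23, n_fish = 25)
  prof <- true_speed_profiles(sim)
  sw <- sensitivity_sweep(prof, thresholds = c(40, 60, 80))
  expect_equal(nrow(sw), 9)
  # the synthetic modes are disjoint across 40-80: identical classifications
  # under the mean rule at all three thresholds
  mean_counts <- sw$n_response[sw$rule == "mean"]
  expect_true(all(mean_counts == mean_counts[1]))
  # threshold 0: every trial moves, so every trial is a response;
  # threshold Inf: none are
  ext <- sensitivity_sweep(prof, thresholds = c(0, Inf), rules = "mean")
  expect_equal(ext$n_response[ext$threshold == 0], nrow(sim$trials))
  expect_equal(ext$n_response[is.infinite(ext$threshold)], 0)
})

test_that("fast-start summaries: conservation and responder counting", {
  sim <- small_faststart_sim(seed = 77, n_fish = 60)
  prof <- true_speed_profiles(sim)
  cl <- classify_trials(prof, 60)
  meta <- sim$trials
  meta$experimental_day <- 1 + (meta$fish_id %% 7)
  out <- summarize_faststarts(prof, cl, meta)
  # responders + non-responders = total, per fish
  expect_equal(sum(out$rates$n_trials), nrow(sim$trials))
  expect_equal(sum(out$rates$n_response), sum(cl$response))
  expect_equal(nrow(out$summaries), sum(cl$response))
  # summary count ~ responder fraction (binomial tolerance)
  n <- nrow(sim$trials)
  expect_lt(abs(nrow(out$summaries) / n - 0.33), 3 * sqrt(0.33 * 0.67 / n))
  # all-responder set: one summary per trial
  simR <- simulate_fast_start_trials(fast_start_sim_params(
    n_fish = 6, trials_per_fish = 1, trial_retention = 1, responder_fraction = 1,
    seed = 2))
  profR <- true_speed_profiles(simR)
  clR <- classify_trials(profR, 60)
  outR <- summarize_faststarts(profR, clR, simR$trials)
  expect_equal(nrow(outR$summaries), nrow(simR$trials))
})

test_that("the pooled simulated experiment yields a valley near the configured default", {
  sim <- simulate_fast_start_trials(fast_start_sim_params(seed = 101))
  windowed <- extract_response_window(true_speed_profiles(sim))
  th <- suppressWarnings(estimate_response_threshold(windowed$v))
  expect_false(th$fallback)
  # the valley separates the non-responder mode (<= ~30 mm/s) from the
  # responder mode (>= ~120 mm/s)
  expect_gt(th$threshold, 30)
  expect_lt(th$threshold, 120)
})
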