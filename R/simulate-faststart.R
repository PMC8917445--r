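#' Simulate fast-start startle trials with ground truth
#'
#' Each trial is a latent responder or non-responder. The centroid speed is a
#' constant slow baseline plus a single smooth pulse (fast rise, slower
#' decay) whose peak speed is drawn from the responder or non-responder
#' distribution and whose onset follows the latency distribution, so
#' responder pulses peak inside the 0-0.157 s response window. Each clip
#' starts `acclimation_s` before the stimulus (negative `time_s`), during
#' which the fish cruises and settles exponentially towards the baseline
#' drift. Positions are the time-integral of the speed along a heading that
#' is specularly reflected at the dish wall before any step that would
#' leave the arena, so every emitted step is a straight segment of exactly
#' `v * dt` and the polyline path length equals the speed integral;
#' reflections are counted in the trial metadata.
#'
#' The generator draws every trial from a deterministic substream of the
#' root seed ([derive_seed()]), so identical parameters give bit-identical
#' output and single trials can be regenerated in isolation.
#'
#' @param params a [fast_start_sim_params()] object.
#' @return a list of class `faststart_sim` with elements
#'   \describe{
#'     \item{trials}{tibble of per-trial truth: `fish_id`, `trial_id`,
#'       `trial_index`, `dish_label`, `responder`, `true_peak_speed`
#'       (mm/s), `latency_s`, `n_reflections`.}
#'     \item{tracks}{long tibble: `fish_id`, `trial_id`, `frame` (0-based),
#'       `time_s` (stimulus at 0), `x_mm`, `y_mm` (origin at dish centre).}
#'     \item{speeds}{long tibble of the true (noise-free) speed per frame:
#'       `fish_id`, `trial_id`, `frame`, `time_s`, `v_true` (mm/s).}
#'     \item{params}{the input parameters.}
#'   }
#' @export
simulate_fast_start_trials <- function(params) {
  stopifnot(inherits(params, "faststart_sim_params"))
  dt <- 1 / params$frame_rate
  n_pre <- ceiling(params$acclimation_s / dt)
  times <- (seq_len(n_pre + floor(params$duration / dt) + 1) - n_pre - 1) * dt
  n_frames <- length(times)
  r_max <- params$dish_diameter_mm / 2 - 4 # keep a 7 mm fish clear of the wall

  trial_meta <- list()
  track_list <- list()
  speed_list <- list()
  trial_id <- 0L

  for (fish in seq_len(params$n_fish)) {
    for (idx in seq_len(params$trials_per_fish)) {
      set.seed(derive_seed(params$seed, "faststart", fish, idx))
      if (stats::runif(1) > params$trial_retention) next
      trial_id <- trial_id + 1L

      responder <- stats::runif(1) < params$responder_fraction
      spec <- if (responder) params$responder_peak_speed else params$nonresponder_peak_speed
      peak <- max(stats::rnorm(1, spec$mean, spec$sd), params$baseline_speed)
      latency <- min(max(stats::rnorm(1, params$latency$mean, params$latency$sd), 0.02), 0.13)

      # cruise settling to baseline before the stimulus, pulse after
      v <- params$baseline_speed +
        (peak - params$baseline_speed) *
          speed_pulse(times - latency, params$pulse_shape$rise, params$pulse_shape$decay)
      pre <- times < 0
      v[pre] <- params$baseline_speed +
        (params$cruise_speed - params$baseline_speed) * (1 - exp(times[pre] / 0.05))
      if (params$speed_jitter > 0) {
        v <- pmax(v + stats::rnorm(n_frames, 0, params$speed_jitter), 0)
      }

      start_angle <- stats::runif(1, 0, 2 * pi)
      p0 <- stats::runif(1, 0.3, 0.8) * r_max * c(cos(start_angle), sin(start_angle))
      heading <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(heading), sin(heading))

      walk <- .integrate_speed(v, dt, p0, u, r_max)
      pos <- walk$pos
      n_refl <- walk$n_reflections

      trial_meta[[trial_id]] <- tibble::tibble(
        fish_id = fish, trial_id = trial_id, trial_index = idx,
        dish_label = paste0("P", (fish - 1L) %% 5L + 1L),
        responder = responder, true_peak_speed = peak,
        latency_s = latency, n_reflections = n_refl)
      track_list[[trial_id]] <- tibble::tibble(
        fish_id = fish, trial_id = trial_id, frame = seq_len(n_frames) - 1L,
        time_s = times, x_mm = pos[, 1], y_mm = pos[, 2])
      speed_list[[trial_id]] <- tibble::tibble(
        fish_id = fish, trial_id = trial_id, frame = seq_len(n_frames) - 1L,
        time_s = times, v_true = v)
    }
  }
  if (trial_id == 0L) {
    stop("no trials retained; increase `n_fish` or `trial_retention`", call. = FALSE)
  }
  structure(
    list(trials = dplyr::bind_rows(trial_meta),
         tracks = dplyr::bind_rows(track_list),
         speeds = dplyr::bind_rows(speed_list),
         params = params),
    class = "faststart_sim")
}

# integrate a speed series into positions confined to the circle |p| <= r.
# Reflection happens *before* a step that would exit: the heading is
# specularly reflected about the local wall tangent (fallback: turned
# straight inward), so every emitted step is straight with length exactly
# v[k] * dt and the polyline length equals the left-Riemann speed integral.
.integrate_speed <- function(v, dt, p0, u, r, headings = NULL) {
  n <- length(v)
  orig <- headings # heading change points (bout onsets) survive reflections
  pos <- matrix(NA_real_, n, 2)
  pos[1, ] <- p <- p0
  n_refl <- 0L
  for (k in seq_len(n - 1)) {
    if (!is.null(headings)) u <- c(cos(headings[k]), sin(headings[k]))
    step <- v[k] * dt
    q <- p + step * u
    if (sqrt(sum(q^2)) > r) {
      n_refl <- n_refl + 1L
      nrm <- p / sqrt(sum(p^2))
      u <- u - 2 * max(sum(u * nrm), 0) * nrm
      q <- p + step * u
      if (sqrt(sum(q^2)) > r) {
        u <- -nrm
        q <- p + step * u
      }
      if (!is.null(headings) && k < n - 1) {
        later <- (k + 1):(n - 1)
        nxt <- later[orig[later] != orig[k]][1]
        end <- if (is.na(nxt)) n - 1 else nxt - 1
        headings[k:end] <- atan2(u[2], u[1])
      }
    }
    p <- q
    pos[k + 1, ] <- p
  }
  list(pos = pos, n_reflections = n_refl)
}
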