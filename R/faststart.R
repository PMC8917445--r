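#' Extract the stimulus-locked response window from a speed profile
#'
#' The fast-start response is measured over a fixed interval after the
#' weight release (stimulus at t = 0); the default 0-0.157 s window is long
#' enough to capture the whole manoeuvre and includes the pre-impact
#' baseline. The profile must cover the window.
#'
#' @param profile speed-profile tibble with `frame`, `time_s` (stimulus at
#'   0), `v` and optionally `valid`.
#' @param window two-element numeric, seconds.
#' @return the rows of `profile` with `window[1] <= time_s <= window[2]`.
#' @export
extract_response_window <- function(profile, window = c(0, 0.157)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  eps <- 1e-9
  ts <- sort(unique(profile$time_s))
  dt <- if (length(ts) > 1) stats::median(diff(ts)) else 0
  # coverage: the first frame at/before the window start, and frames up to
  # within one frame interval of the window end (the window end need not
  # fall on the frame grid)
  if (min(ts) > window[1] + eps || max(ts) < window[2] - dt - eps) {
    stop(sprintf("profile covers %.4f-%.4f s but the response window needs %.3f-%.3f s (frames %d-%d)",
                 min(profile$time_s), max(profile$time_s), window[1], window[2],
                 min(profile$frame), max(profile$frame)), call. = FALSE)
  }
  profile[profile$time_s >= window[1] - eps & profile$time_s <= window[2] + eps, ]
}

#' Across-trial mean speed curve and its peak frame
#'
#' Frame-wise arithmetic mean of speed over all trials aligned on the
#' stimulus (invalid frames excluded per frame). The peak frame anchors the
#' 7-frame classification window; ties go to the earliest frame.
#'
#' @param trials long tibble with `trial_id`, `frame`, `time_s`, `v` and
#'   optionally `valid`, all trials stimulus-aligned on `frame`.
#' @return list with `curve` (tibble `frame`, `time_s`, `mean_speed`,
#'   `n_trials`) and `peak_frame`.
#' @export
mean_speed_curve <- function(trials) {
  if (length(unique(trials$trial_id)) < 2) {
    stop("mean speed curve needs at least 2 trials", call. = FALSE)
  }
  ok <- if ("valid" %in% names(trials)) trials$valid else rep(TRUE, nrow(trials))
  ok <- ok & is.finite(trials$v)
  if (!any(ok)) stop("no aligned valid frames across trials", call. = FALSE)
  curve <- trials[ok, ] |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(time_s = .data$time_s[1],
                     mean_speed = mean(.data$v),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$frame)
  list(curve = curve, peak_frame = curve$frame[which.max(curve$mean_speed)])
}

#' Estimate the response threshold from the pooled speed histogram
#'
#' Pools all instantaneous speeds observed in the response windows of all
#' trials, histograms them, applies a light moving-average smoothing, finds
#' the two most prominent local maxima (topographic prominence; the
#' non-responder and responder modes), and places the threshold at the
#' bin-centre speed of the minimum-count bin strictly between them (the
#' histogram valley). Ties go to the lower speed. If fewer than two
#' sufficiently prominent, separated peaks exist, or the valley between
#' them is too shallow to indicate genuine bimodality, the configured
#' default (60 mm/s) is returned with the fallback flag set.
#'
#' @param speeds pooled instantaneous speeds, mm/s.
#' @param bin_width histogram bin width, mm/s.
#' @param smooth_bins moving-average length in bins.
#' @param min_peak_separation minimum separation between the two modes, in
#'   bins.
#' @param min_prominence_frac a local maximum counts as a mode only if its
#'   topographic prominence is at least this fraction of its own height
#'   (scale-free, so a small responder mode still counts while noise
#'   ripples on a shoulder do not).
#' @param max_valley_frac the valley must be at most this fraction of the
#'   smaller mode's height, otherwise the histogram is declared unimodal.
#' @param min_mode_mass each side of the valley must contain at least this
#'   fraction of all pooled speeds, so a handful of tail outliers cannot
#'   masquerade as a mode.
#' @param default_threshold fallback threshold, mm/s.
#' @return an object of class `response_threshold`: list with `threshold`
#'   (mm/s), `histogram` (tibble `bin_lo`, `bin_hi`, `mid`, `count`,
#'   `smoothed`), `peak_bins` (indices, low mode first), `valley_bin`,
#'   `fallback`, and the binning parameters.
#' @export
estimate_response_threshold <- function(speeds, bin_width = 2, smooth_bins = 3,
                                        min_peak_separation = 3,
                                        min_prominence_frac = 0.2,
                                        max_valley_frac = 0.8,
                                        min_mode_mass = 0.02,
                                        default_threshold = 60) {
  speeds <- speeds[is.finite(speeds)]
  if (length(speeds) == 0) stop("no speeds to histogram", call. = FALSE)
  assert_pos(bin_width, "bin_width")
  lo <- min(0, floor(min(speeds) / bin_width) * bin_width)
  breaks <- seq(lo, max(speeds) + bin_width, by = bin_width)
  h <- graphics::hist(speeds, breaks = breaks, plot = FALSE, right = FALSE)
  counts <- h$counts
  sm <- moving_average(counts, smooth_bins)

  hist_tbl <- tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                             mid = h$mids, count = counts, smoothed = sm)
  base <- list(histogram = hist_tbl, bin_width = bin_width,
               smooth_bins = smooth_bins,
               min_peak_separation = min_peak_separation)
  give_up <- function() {
    warning(sprintf("speed histogram is not bimodal; falling back to the default threshold (%g mm/s)",
                    default_threshold))
    structure(c(list(threshold = default_threshold,
                     peak_bins = c(NA_integer_, NA_integer_),
                     valley_bin = NA_integer_, fallback = TRUE), base),
              class = "response_threshold")
  }

  prom <- .peak_prominences(sm)
  cand <- prom$idx[prom$prominence >= min_prominence_frac * sm[prom$idx]]
  if (length(cand) < 2) return(give_up())
  # most prominent peak, then the most prominent one far enough from it
  cand <- cand[order(-prom$prominence[match(cand, prom$idx)], cand)]
  p1 <- cand[1]
  rest <- cand[abs(cand - p1) >= min_peak_separation]
  if (length(rest) == 0) return(give_up())
  peaks <- sort(c(p1, rest[1]))

  # deep valleys can be wide and flat, where the single argmin is dominated
  # by count noise: treat all bins within one Poisson standard deviation of
  # the minimum as tied and take the middle of that plateau
  between <- (peaks[1] + 1):(peaks[2] - 1)
  vmin <- min(sm[between])
  plateau <- between[sm[between] <= vmin + sqrt(vmin + 1)]
  valley <- plateau[ceiling(length(plateau) / 2)]
  if (sm[valley] > max_valley_frac * min(sm[peaks])) return(give_up())
  mass_low <- sum(counts[seq_len(valley)])
  if (min(mass_low, sum(counts) - mass_low) < min_mode_mass * sum(counts)) {
    return(give_up())
  }
  structure(c(list(threshold = h$mids[valley], peak_bins = peaks,
                   valley_bin = valley, fallback = FALSE), base),
            class = "response_threshold")
}

# topographic prominence of every local maximum of a series: height above
# the higher of the two saddles on the paths towards higher ground
.peak_prominences <- function(sm) {
  n <- length(sm)
  padded <- c(-Inf, sm, -Inf)
  idx <- which(padded[2:(n + 1)] > padded[1:n] & padded[2:(n + 1)] >= padded[3:(n + 2)])
  prominence <- vapply(idx, function(i) {
    h <- sm[i]
    key <- -Inf
    for (dir in c(-1L, 1L)) {
      j <- i + dir
      run_min <- h
      side <- NA_real_
      while (j >= 1 && j <= n) {
        if (sm[j] > h) { side <- run_min; break }
        run_min <- min(run_min, sm[j])
        j <- j + dir
      }
      if (!is.na(side)) key <- max(key, side)
    }
    if (is.infinite(key)) key <- min(sm) # global maximum
    h - key
  }, numeric(1))
  list(idx = idx, prominence = prominence)
}

#' @export
print.response_threshold <- function(x, ...) {
  cat(sprintf("Response threshold: %.1f mm/s%s\n", x$threshold,
              if (x$fallback) " (fallback default; histogram not bimodal)" else ""))
  if (!x$fallback) {
    cat(sprintf("  modes at %.1f and %.1f mm/s, valley at bin %d (bin width %g mm/s)\n",
                x$histogram$mid[x$peak_bins[1]], x$histogram$mid[x$peak_bins[2]],
                x$valley_bin, x$bin_width))
  }
  invisible(x)
}

#' Classify one trial as response / no response
#'
#' Applies the 7-frame-window rule: a trial is a fast-start response if its
#' speed during the window centred on the peak of the across-trial mean
#' speed curve exceeds the threshold (strictly). The default reading of
#' "speed during the window" is the window mean; "any frame exceeds" and
#' "all frames exceed" are selectable alternatives. Windows that would
#' leave the response interval are clipped and flagged.
#'
#' @param profile one trial's response-window profile (`frame`, `v`,
#'   optionally `valid`).
#' @param threshold speed threshold, mm/s (a number or a
#'   `response_threshold`).
#' @param peak_frame centre frame of the classification window (from
#'   [mean_speed_curve()]).
#' @param win window length in frames (odd), default 7.
#' @param rule `"mean"`, `"any"` or `"all"`.
#' @return list: `response` (logical, `NA` if unclassifiable), `clipped`,
#'   `unclassifiable`, `rule`, `window_frames`.
#' @export
classify_response <- function(profile, threshold, peak_frame, win = 7,
                              rule = c("mean", "any", "all")) {
  rule <- match.arg(rule)
  stopifnot(win %% 2 == 1)
  if (inherits(threshold, "response_threshold")) threshold <- threshold$threshold
  half <- (win - 1) %/% 2
  want <- (peak_frame - half):(peak_frame + half)
  have <- intersect(want, profile$frame)
  clipped <- length(have) < win
  ok <- profile$frame %in% have & is.finite(profile$v)
  if ("valid" %in% names(profile)) ok <- ok & profile$valid
  if (!any(ok)) {
    return(list(response = NA, clipped = clipped, unclassifiable = TRUE,
                rule = rule, window_frames = have))
  }
  v <- profile$v[ok]
  response <- switch(rule,
                     mean = mean(v) > threshold,
                     any = any(v > threshold),
                     all = all(v > threshold))
  list(response = response, clipped = clipped, unclassifiable = FALSE,
       rule = rule, window_frames = have)
}

#' Classify every trial in a set
#'
#' Convenience wrapper: extracts response windows, finds the mean-curve
#' peak, and applies [classify_response()] to each trial.
#'
#' @param trials long tibble (`trial_id`, `frame`, `time_s`, `v`, optional
#'   `valid`), stimulus-aligned.
#' @param threshold number or `response_threshold`.
#' @param window response window, s.
#' @param win,rule see [classify_response()].
#' @param peak_frame optional fixed centre frame; default from
#'   [mean_speed_curve()] over the windowed trials.
#' @return tibble: `trial_id`, `response`, `clipped`, `unclassifiable`,
#'   `rule`, `peak_frame`, `threshold`.
#' @export
classify_trials <- function(trials, threshold, window = c(0, 0.157),
                            win = 7, rule = c("mean", "any", "all"),
                            peak_frame = NULL) {
  rule <- match.arg(rule)
  if (inherits(threshold, "response_threshold")) threshold <- threshold$threshold
  windowed <- extract_response_window(trials, window)
  if (is.null(peak_frame)) peak_frame <- mean_speed_curve(windowed)$peak_frame
  ids <- unique(windowed$trial_id)
  res <- lapply(ids, function(id) {
    cl <- classify_response(windowed[windowed$trial_id == id, ], threshold,
                            peak_frame, win, rule)
    tibble::tibble(trial_id = id, response = cl$response, clipped = cl$clipped,
                   unclassifiable = cl$unclassifiable)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(rule = rule, peak_frame = peak_frame, threshold = threshold)
}

#' Summarise classified fast-start trials
#'
#' Kinematic summaries (means and quantile-mean maxima over the response
#' window) for trials classified as responses, plus a response-rate table
#' per fish (and per experimental day when available).
#'
#' @param trials long profile tibble (`trial_id`, `frame`, `time_s`, `v`,
#'   optional `a`, `valid`).
#' @param classifications output of [classify_trials()].
#' @param meta per-trial metadata tibble with `trial_id`, `fish_id` and
#'   optionally `experimental_day`, `trial_index`, `dish_label`.
#' @param window response window, s.
#' @param q quantile for [robust_extremum()].
#' @return list with `summaries` (one row per responding trial) and
#'   `rates` (responders / total per fish, and per day if present).
#' @export
summarize_faststarts <- function(trials, classifications, meta,
                                 window = c(0, 0.157), q = 0.95) {
  stopifnot(all(c("trial_id", "fish_id") %in% names(meta)))
  cls <- dplyr::left_join(classifications, meta, by = "trial_id")
  windowed <- extract_response_window(trials, window)
  resp_ids <- cls$trial_id[!is.na(cls$response) & cls$response]
  summaries <- dplyr::bind_rows(lapply(resp_ids, function(id) {
    s <- summarize_kinematics(windowed[windowed$trial_id == id, ], q = q,
                              segment = "faststart")
    s$fish_id <- cls$fish_id[cls$trial_id == id]
    s$trial_id <- id
    s
  }))
  by_cols <- intersect(c("fish_id", "experimental_day"), names(cls))
  rates <- cls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by_cols))) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_response = sum(.data$response, na.rm = TRUE),
                     response_rate = .data$n_response / .data$n_trials,
                     .groups = "drop")
  list(summaries = summaries, rates = rates)
}

#' Threshold / rule sensitivity sweep
#'
#' Re-classifies the trial set under the full cross of thresholds and
#' window rules, reporting response counts and summary statistics of the
#' responders, to check how robust downstream conclusions are to the
#' threshold choice.
#'
#' @param trials long profile tibble, stimulus-aligned.
#' @param thresholds numeric vector of thresholds, mm/s.
#' @param rules subset of `c("mean", "any", "all")`.
#' @param window,win see [classify_trials()].
#' @param q quantile for the responder summary statistics.
#' @return tibble: `threshold`, `rule`, `n_trials`, `n_response`,
#'   `response_rate`, `mean_v_mean`, `mean_v_max` (means over responders;
#'   `NA` when there are none).
#' @export
sensitivity_sweep <- function(trials, thresholds,
                              rules = c("mean", "any", "all"),
                              window = c(0, 0.157), win = 7, q = 0.95) {
  stopifnot(length(thresholds) >= 1)
  windowed <- extract_response_window(trials, window)
  peak <- mean_speed_curve(windowed)$peak_frame
  grid <- expand.grid(threshold = thresholds, rule = rules,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cl <- classify_trials(windowed, grid$threshold[g], window = window,
                          win = win, rule = grid$rule[g], peak_frame = peak)
    resp_ids <- cl$trial_id[!is.na(cl$response) & cl$response]
    if (length(resp_ids) > 0) {
      sm <- dplyr::bind_rows(lapply(resp_ids, function(id) {
        summarize_kinematics(windowed[windowed$trial_id == id, ], q = q,
                             segment = "faststart")
      }))
      mvm <- mean(sm$v_mean); mvx <- mean(sm$v_max)
    } else {
      mvm <- NA_real_; mvx <- NA_real_
    }
    tibble::tibble(threshold = grid$threshold[g], rule = grid$rule[g],
                   n_trials = nrow(cl), n_response = length(resp_ids),
                   response_rate = length(resp_ids) / nrow(cl),
                   mean_v_mean = mvm, mean_v_max = mvx)
  })
  dplyr::bind_rows(rows)
}

#' True (noise-free) speed profiles of simulated trials
#'
#' Reshapes the generator's ground-truth speeds into the long profile
#' format the classification functions consume, bypassing tracking and
#' smoothing.
#'
#' @param sim a [simulate_fast_start_trials()] result.
#' @return long tibble: `fish_id`, `trial_id`, `frame`, `time_s`, `v`,
#'   `valid`.
#' @export
true_speed_profiles <- function(sim) {
  stopifnot(inherits(sim, "faststart_sim"))
  tibble::tibble(fish_id = sim$speeds$fish_id, trial_id = sim$speeds$trial_id,
                 frame = sim$speeds$frame, time_s = sim$speeds$time_s,
                 v = sim$speeds$v_true, valid = TRUE)
}
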