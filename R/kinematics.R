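#' Savitzky-Golay smoothing of a track with derivatives
#'
#' Fits a local polynomial of the given order over a sliding odd-length
#' window to each coordinate, per contiguous run of valid frames, and
#' returns the fitted positions together with first and second derivatives
#' from the fitted coefficients. Edge frames (within half a window of a run
#' boundary, where the fit is one-sided) are flagged lower-confidence. Runs
#' shorter than the window are invalidated with a warning.
#'
#' @param track tibble with `frame`, `time_s` (constant step), `x_mm`,
#'   `y_mm` and optionally `valid`.
#' @param window odd window length in frames.
#' @param order polynomial degree (`< window`).
#' @return the track with columns `x_s`, `y_s` (smoothed positions, mm),
#'   `dx`, `dy` (mm/s), `ddx`, `ddy` (mm/s^2), updated `valid`, and `edge`.
#' @export
smooth_track <- function(track, window = 7, order = 2) {
  stopifnot(window %% 2 == 1, order < window)
  valid <- if ("valid" %in% names(track)) track$valid else rep(TRUE, nrow(track))
  dt_all <- diff(track$time_s)
  dt <- stats::median(dt_all)
  if (any(abs(dt_all - dt) > 1e-9 * max(1, abs(dt)))) {
    stop("track timestamps must have a constant frame interval", call. = FALSE)
  }

  n <- nrow(track)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("x_s", "y_s", "dx", "dy", "ddx", "ddy")))
  edge <- rep(FALSE, n)
  half <- (window - 1) %/% 2
  n_short <- 0L

  r <- rle(valid)
  hi_all <- cumsum(r$lengths)
  lo_all <- hi_all - r$lengths + 1
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    idx <- lo_all[j]:hi_all[j]
    if (length(idx) < window) {
      valid[idx] <- FALSE
      n_short <- n_short + 1L
      next
    }
    for (axis in c("x_mm", "y_mm")) {
      z <- track[[axis]][idx]
      cols <- if (axis == "x_mm") c(1, 3, 5) else c(2, 4, 6)
      out[idx, cols[1]] <- signal::sgolayfilt(z, p = order, n = window, m = 0)
      out[idx, cols[2]] <- signal::sgolayfilt(z, p = order, n = window, m = 1, ts = dt)
      if (order >= 2) {
        out[idx, cols[3]] <- signal::sgolayfilt(z, p = order, n = window, m = 2, ts = dt)
      }
    }
    edge[idx[c(seq_len(half), length(idx) - seq_len(half) + 1)]] <- TRUE
  }
  if (n_short > 0) {
    warning(sprintf("%d valid run(s) shorter than the %d-frame window were invalidated",
                    n_short, window))
  }
  res <- track
  res$valid <- valid
  for (nm in colnames(out)) res[[nm]] <- out[, nm]
  res$edge <- edge
  attr(res, "smoothing") <- list(window = window, order = order, dt = dt)
  res
}

#' Compute a speed and acceleration profile from a track
#'
#' Speed is the magnitude of the smoothed velocity vector; acceleration is,
#' by default, the magnitude of the second-derivative vector
#' (`"vector"` convention). The signed rate of change of speed,
#' d|v|/dt, is available as the `"tangential"` convention.
#'
#' @param track calibrated track tibble (see [smooth_track()]).
#' @param window,order Savitzky-Golay parameters.
#' @param accel `"vector"` (magnitude of vector acceleration) or
#'   `"tangential"` (signed d|v|/dt).
#' @return a tibble: `fish_id` (if present), `frame`, `time_s`, `v` (mm/s),
#'   `a` (mm/s^2), `valid`, `edge`; smoothing settings in the `smoothing`
#'   attribute.
#' @export
compute_speed_profile <- function(track, window = 7, order = 2,
                                  accel = c("vector", "tangential")) {
  accel <- match.arg(accel)
  sm <- smooth_track(track, window, order)
  if (!any(sm$valid)) {
    warning("all frames invalid; empty profile")
  }
  v <- sqrt(sm$dx^2 + sm$dy^2)
  a <- if (accel == "vector") {
    sqrt(sm$ddx^2 + sm$ddy^2)
  } else {
    .tangential_accel(v, sm$valid, attr(sm, "smoothing")$dt, window, order)
  }
  out <- tibble::tibble(frame = sm$frame, time_s = sm$time_s,
                        v = v, a = a, valid = sm$valid, edge = sm$edge)
  if ("fish_id" %in% names(sm)) out <- dplyr::bind_cols(tibble::tibble(fish_id = sm$fish_id), out)
  attr(out, "smoothing") <- c(attr(sm, "smoothing"), list(accel = accel))
  out
}

.tangential_accel <- function(v, valid, dt, window, order) {
  a <- rep(NA_real_, length(v))
  r <- rle(valid & !is.na(v))
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1
  for (j in seq_along(r$lengths)) {
    if (!r$values[j] || r$lengths[j] < window) next
    idx <- lo[j]:hi[j]
    a[idx] <- signal::sgolayfilt(v[idx], p = order, n = window, m = 1, ts = dt)
  }
  a
}

#' Robust maximum: mean above a quantile
#'
#' Extreme speed and acceleration values are sensitive to measurement
#' noise, so the "maximum" is summarised as the arithmetic mean of the
#' values strictly greater than the q-quantile (linear-interpolation
#' quantile, R type 7) rather than the single largest value. If no value
#' exceeds the quantile (e.g. all values equal), the sample maximum is
#' returned.
#'
#' @param values numeric vector (NAs dropped).
#' @param q quantile in `[0, 1)`, default 0.95.
#' @return the quantile-mean robust maximum.
#' @examples
#' robust_extremum(1:100) # mean of 96..100 = 98
#' @export
robust_extremum <- function(values, q = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("robust_extremum: no finite values", call. = FALSE)
  assert_prob(q, "q")
  qv <- stats::quantile(values, q, names = FALSE, type = 7)
  above <- values > qv
  if (!any(above)) return(max(values))
  mean(values[above])
}

#' Summarise a speed profile over a frame subset
#'
#' Means and quantile-mean robust maxima of speed and acceleration over the
#' valid frames of the given subset.
#'
#' @param profile a [compute_speed_profile()] tibble (or any tibble with
#'   `v`, `a`, `valid`, `frame`).
#' @param frames optional integer vector of frame indices to restrict to
#'   (default: all).
#' @param q quantile for [robust_extremum()].
#' @param segment label recorded in the output (and in error messages).
#' @return a one-row tibble: `fish_id` (if present), `segment`, `v_mean`,
#'   `v_max`, `a_mean`, `a_max`, `n_frames`, `q`.
#' @export
summarize_kinematics <- function(profile, frames = NULL, q = 0.95,
                                 segment = NA_character_) {
  sel <- profile$valid & is.finite(profile$v)
  if (!is.null(frames)) sel <- sel & profile$frame %in% frames
  if (!any(sel)) {
    stop(sprintf("no valid frames in segment '%s'", segment), call. = FALSE)
  }
  v <- profile$v[sel]
  has_a <- "a" %in% names(profile) && any(is.finite(profile$a[sel]))
  a <- if (has_a) profile$a[sel][is.finite(profile$a[sel])] else NULL
  tibble::tibble(
    fish_id = if ("fish_id" %in% names(profile)) profile$fish_id[which(sel)[1]] else NA,
    segment = segment,
    v_mean = mean(v),
    v_max = robust_extremum(v, q),
    a_mean = if (has_a) mean(a) else NA_real_,
    a_max = if (has_a) robust_extremum(a, q) else NA_real_,
    n_frames = sum(sel),
    q = q)
}
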