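#' Simulate one feeding session with ground-truth bouts
#'
#' Emulates the feeding assay: 5 min without food (control), a short
#' food-supply interval in which the experimenter disturbs the arena, then
#' 5 min with food (feeding). Swimming bouts arrive as a homogeneous Poisson
#' process at the segment's rate; each bout adds a smooth speed pulse with a
#' peak drawn from the bout-speed distribution, and the fish is otherwise
#' still. During the supply interval the speed trace is replaced by
#' large-magnitude disturbance motion that downstream segmentation must
#' discard. Positions integrate the speed along a per-bout random heading,
#' reflected at the dish wall.
#'
#' @param params a [feeding_sim_params()] object.
#' @param fish_id identifier carried through the outputs.
#' @return a list of class `feeding_session_sim` with elements
#'   \describe{
#'     \item{profile}{tibble: `fish_id`, `frame` (0-based), `time_s`, `v`
#'       (mm/s, true speed), `valid` (all `TRUE`).}
#'     \item{track}{tibble: `fish_id`, `frame`, `time_s`, `x_mm`, `y_mm`
#'       (origin at dish centre, 55 mm dish).}
#'     \item{events}{tibble: `event` (control/supply/feeding), `t_start_s`,
#'       `t_end_s` (half-open intervals).}
#'     \item{bouts}{tibble of true bouts: `segment`, `onset_s`,
#'       `peak_speed`.}
#'     \item{truth}{tibble: `segment`, `true_mean_speed` -- the mean of the
#'       true speed over the segment's frames.}
#'     \item{params}{the input parameters.}
#'   }
#' @export
simulate_feeding_session <- function(params, fish_id = 1L) {
  stopifnot(inherits(params, "feeding_sim_params"))
  dt <- 1 / params$frame_rate
  supply_start <- params$control_duration
  feeding_start <- supply_start + params$supply_gap
  total <- feeding_start + params$feeding_duration
  times <- seq(0, total - dt / 2, by = dt)
  n <- length(times)

  events <- tibble::tibble(
    event = c("control", "supply", "feeding"),
    t_start_s = c(0, supply_start, feeding_start),
    t_end_s = c(supply_start, feeding_start, total))
  if (params$supply_gap == 0) events <- events[events$event != "supply", ]

  set.seed(derive_seed(params$seed, "feeding", fish_id, "bouts"))
  draw_bouts <- function(rate, t0, t1, segment) {
    n_b <- stats::rpois(1, rate * (t1 - t0))
    if (n_b == 0) {
      return(tibble::tibble(segment = character(), onset_s = numeric(),
                            peak_speed = numeric(), heading = numeric()))
    }
    tibble::tibble(
      segment = segment,
      onset_s = sort(stats::runif(n_b, t0, t1)),
      peak_speed = pmax(stats::rnorm(n_b, params$bout_speed$mean, params$bout_speed$sd), 0),
      heading = stats::runif(n_b, 0, 2 * pi))
  }
  bouts <- dplyr::bind_rows(
    draw_bouts(params$bout_rate_control, 0, supply_start, "control"),
    draw_bouts(params$bout_rate_feeding, feeding_start, total, "feeding"))

  v <- numeric(n)
  heading <- rep(stats::runif(1, 0, 2 * pi), n)
  for (b in seq_len(nrow(bouts))) {
    rel <- times - bouts$onset_s[b]
    active <- rel > 0 & rel < 20 * params$bout_shape$decay
    v[active] <- v[active] +
      bouts$peak_speed[b] * speed_pulse(rel[active], params$bout_shape$rise,
                                        params$bout_shape$decay)
    heading[times >= bouts$onset_s[b]] <- bouts$heading[b]
  }
  in_supply <- times >= supply_start & times < feeding_start
  if (any(in_supply)) {
    set.seed(derive_seed(params$seed, "feeding", fish_id, "disturbance"))
    v[in_supply] <- abs(stats::rnorm(sum(in_supply), params$disturbance_speed$mean,
                                     params$disturbance_speed$sd))
  }

  # integrate positions inside a 55 mm dish, reflecting at the wall
  r_max <- 55 / 2 - 4
  walk <- .integrate_speed(v, dt, p0 = c(0, 0),
                           u = c(cos(heading[1]), sin(heading[1])),
                           r = r_max, headings = heading)
  pos <- walk$pos

  seg <- rep(NA_character_, n)
  for (e in seq_len(nrow(events))) {
    seg[times >= events$t_start_s[e] & times < events$t_end_s[e]] <- events$event[e]
  }
  truth <- tibble::tibble(
    segment = c("control", "feeding"),
    true_mean_speed = c(mean(v[seg == "control" & !is.na(seg)]),
                        mean(v[seg == "feeding" & !is.na(seg)])))

  structure(
    list(profile = tibble::tibble(fish_id = fish_id, frame = seq_len(n) - 1L,
                                  time_s = times, v = v, valid = TRUE),
         track = tibble::tibble(fish_id = fish_id, frame = seq_len(n) - 1L,
                                time_s = times, x_mm = pos[, 1], y_mm = pos[, 2]),
         events = events, bouts = bouts[c("segment", "onset_s", "peak_speed")],
         truth = truth, params = params),
    class = "feeding_session_sim")
}
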