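#' Split a feeding recording into control and feeding segments
#'
#' Assigns every frame to a session segment by half-open intervals
#' `[t_start, t_end)`. Frames inside the food-supply interval (experimenter
#' disturbance) belong to neither analysis segment and are excluded; frames
#' outside all events stay unassigned. No frame is ever double-counted.
#'
#' @param profile speed-profile tibble with `time_s` (and any other
#'   columns, carried through).
#' @param events tibble with `event` (`"control"`, `"supply"`,
#'   `"feeding"`), `t_start_s`, `t_end_s`.
#' @return list with `profile` (input plus a `segment` column, `NA` when
#'   out of window) and `counts` (frames per segment, including
#'   `supply` and `out_of_window`).
#' @export
split_session <- function(profile, events) {
  stopifnot(all(c("event", "t_start_s", "t_end_s") %in% names(events)))
  if (any(events$t_end_s < events$t_start_s)) {
    stop("events with t_end_s < t_start_s", call. = FALSE)
  }
  if (any(events$t_start_s < min(profile$time_s) - 1e-9) ||
      any(events$t_start_s > max(profile$time_s) + 1e-9)) {
    stop("event times outside the recording", call. = FALSE)
  }
  ev <- events[order(events$t_start_s), ]
  if (nrow(ev) > 1) {
    overlaps <- which(ev$t_start_s[-1] < ev$t_end_s[-nrow(ev)])
    if (length(overlaps) > 0) {
      pairs <- paste(sprintf("%s/%s", ev$event[overlaps], ev$event[overlaps + 1]),
                     collapse = ", ")
      stop("overlapping events: ", pairs, call. = FALSE)
    }
  }
  seg <- rep(NA_character_, nrow(profile))
  for (e in seq_len(nrow(ev))) {
    seg[profile$time_s >= ev$t_start_s[e] & profile$time_s < ev$t_end_s[e]] <- ev$event[e]
  }
  out <- profile
  out$segment <- seg
  counts <- tibble::tibble(
    segment = c("control", "supply", "feeding", "out_of_window"),
    n_frames = c(sum(seg == "control", na.rm = TRUE),
                 sum(seg == "supply", na.rm = TRUE),
                 sum(seg == "feeding", na.rm = TRUE),
                 sum(is.na(seg))))
  list(profile = out, counts = counts)
}

#' Summarise one feeding session per period
#'
#' Kinematic summaries of the control and feeding segments (supply frames
#' never contribute), with session metadata attached for export.
#'
#' @param split a [split_session()] result.
#' @param meta list or one-row data frame with `fish_id`, `age_days`,
#'   `treatment`, `experimental_day` and optionally `dish_label`.
#' @param q quantile for [robust_extremum()].
#' @return a two-row tibble (periods `control` and `feeding`) with the
#'   summary and metadata columns.
#' @export
summarize_session <- function(split, meta, q = 0.95) {
  prof <- split$profile
  rows <- lapply(c("control", "feeding"), function(per) {
    sel <- !is.na(prof$segment) & prof$segment == per
    if (!any(sel)) stop(sprintf("empty segment '%s'", per), call. = FALSE)
    s <- summarize_kinematics(prof[sel, ], q = q, segment = per)
    s$fish_id <- meta$fish_id
    s
  })
  out <- dplyr::bind_rows(rows)
  out$age_days <- meta$age_days
  out$treatment <- meta$treatment
  out$experimental_day <- meta$experimental_day
  out$dish_label <- meta$dish_label %||% NA_character_
  dplyr::rename(out, period = "segment")
}

#' Assemble the long-format feeding table
#'
#' One row per fish x age x period, with natural-log transforms of the
#' kinematic summaries appended alongside the raw mm/s (mm/s^2) values, as
#' required by downstream log-scale models. Missing sessions are allowed
#' (and reported); duplicated (fish, age, period) rows are an error.
#'
#' @param sessions list of [summarize_session()] tibbles.
#' @return long tibble: `fish_id`, `age_days`, `treatment`,
#'   `experimental_day`, `dish_label`, `period`, `v_mean`, `v_max`,
#'   `a_mean`, `a_max`, `n_frames`, `q` and `ln_*` columns.
#' @export
build_feeding_table <- function(sessions) {
  stopifnot(length(sessions) >= 1)
  tbl <- dplyr::bind_rows(sessions)
  key <- paste(tbl$fish_id, tbl$age_days, tbl$period)
  if (anyDuplicated(key)) {
    stop("duplicate (fish, age, period) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  expected <- length(unique(tbl$fish_id)) * length(unique(tbl$age_days)) * 2
  if (nrow(tbl) < expected) {
    message(sprintf("feeding table: %d of %d fish x age x period combinations present",
                    nrow(tbl), expected))
  }
  for (col in c("v_mean", "v_max", "a_mean", "a_max")) {
    tbl[[paste0("ln_", col)]] <- ifelse(tbl[[col]] > 0, log(tbl[[col]]), NA_real_)
  }
  tbl[order(tbl$fish_id, tbl$age_days, tbl$period),
      c("fish_id", "age_days", "treatment", "experimental_day", "dish_label",
        "period", "v_mean", "v_max", "a_mean", "a_max", "n_frames", "q",
        "ln_v_mean", "ln_v_max", "ln_a_mean", "ln_a_max")]
}
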