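#' Write / read trajectory tables
#'
#' Trajectory CSVs share one schema between the synthetic generator and the
#' tracker (`fish_id`, `trial_id` where applicable, `frame`, `time_s`,
#' `x_mm`, `y_mm`, plus `valid` / `gap_filled` when produced by tracking),
#' so downstream stages are agnostic to the source. Coordinates are mm with
#' the origin at the dish centre, x rightwards, y downwards; a comment
#' header records the convention.
#'
#' @param tracks a track tibble.
#' @param path CSV path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` a tibble.
#' @export
write_tracks <- function(tracks, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# centroid trajectories; mm, origin at dish centre, x rightwards, y downwards",
               "# frame is 0-based; time_s has a constant frame interval"), con)
  utils::write.csv(as.data.frame(tracks), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Write / read event logs
#'
#' Event CSVs carry `fish_id` (optional), `event`, `t_start_s`, `t_end_s`.
#'
#' @param events an events tibble.
#' @param path CSV path.
#' @return `write_events` returns `path` invisibly; `read_events` a tibble.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
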