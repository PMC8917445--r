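#' Estimate a static background by temporal median
#'
#' The per-pixel median over time is robust to a moving fish as long as the
#' fish occupies each pixel in fewer than half of the frames. At least 11
#' frames are required; for long sequences an evenly spaced subsample keeps
#' the median cheap without losing robustness.
#'
#' @param frames list of greyscale matrices (identical dimensions).
#' @param n_sample maximum number of frames entering the median (evenly
#'   spaced; forced odd).
#' @return a background matrix of the same dimensions.
#' @export
estimate_background <- function(frames, n_sample = 101) {
  if (length(frames) < 11) {
    stop(sprintf("background estimation needs at least 11 frames, got %d",
                 length(frames)), call. = FALSE)
  }
  idx <- .bg_sample_idx(length(frames), n_sample)
  mat <- vapply(frames[idx], as.vector, numeric(length(frames[[1]])))
  matrix(.row_medians(mat), nrow(frames[[1]]), ncol(frames[[1]]))
}

# row-wise median of a numeric matrix, NA-tolerant, via one radix sort
.row_medians <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  k <- m - rowSums(is.na(mat)) # non-NA count per row; NAs sort last
  sorted <- matrix(mat[order(row(mat), mat, na.last = TRUE)], n, m, byrow = TRUE)
  lo <- sorted[cbind(seq_len(n), pmax(1L, (k + 1L) %/% 2L))]
  hi <- sorted[cbind(seq_len(n), pmax(1L, (k + 2L) %/% 2L))]
  out <- (lo + hi) / 2
  out[k == 0] <- NA_real_
  out
}

.bg_sample_idx <- function(n, n_sample) {
  n_use <- min(n, n_sample)
  if (n_use %% 2 == 0) n_use <- n_use - 1
  unique(round(seq(1, n, length.out = n_use)))
}

# second-pass background: recompute the per-pixel median over the sampled
# frames, excluding for each frame a disc around the first-pass fish
# detection, so a dwelling fish cannot imprint itself on the background
.refine_background <- function(stack, bg1, roi, idx, ...) {
  mat <- vapply(stack[idx], as.vector, numeric(length(bg1)))
  nr <- nrow(bg1)
  rows <- matrix(seq_len(nr) - 1, nr, ncol(bg1))
  cols <- matrix(rep(seq_len(ncol(bg1)) - 1, each = nr), nr)
  for (j in seq_along(idx)) {
    seg <- segment_silhouette(stack[[idx[j]]], bg1, roi, ...)
    if (!seg$detected) next
    r_mask <- 2 * sqrt(seg$area_px / pi) + 6
    masked <- (rows - seg$centroid_px[["y"]])^2 +
      (cols - seg$centroid_px[["x"]])^2 <= r_mask^2
    mat[as.vector(masked), j] <- NA_real_
  }
  med <- .row_medians(mat)
  med[!is.finite(med)] <- bg1[!is.finite(med)]
  matrix(med, nr, ncol(bg1))
}

#' Segment the fish silhouette in one dish ROI
#'
#' Thresholds the background difference inside the circular ROI (automatic
#' Otsu threshold by default), labels connected components, and keeps the
#' largest component whose pixel area lies within the area gates. The
#' centroid is the unweighted mean of the component's 0-based pixel
#' coordinates (optionally weighted by the background difference). The
#' assay back-lights the arena, so the fish is a dark silhouette on a
#' bright background; the default `"dark"` polarity uses the signed
#' difference `background - frame`, which also suppresses bright "ghost"
#' artefacts left in the median background by a slow-moving fish.
#'
#' @param frame,background greyscale matrices in `[0, 1]`.
#' @param roi list with `centre_row`, `centre_col` (0-based px) and
#'   `radius` (px).
#' @param min_area_px,max_area_px component-area gates in pixels.
#' @param threshold fixed grey-level threshold on the absolute difference;
#'   `NULL` (default) uses Otsu within the ROI.
#' @param min_contrast minimum peak background difference for a detection;
#'   below this the ROI is declared empty (e.g. frame equal to background).
#' @param polarity `"dark"` (fish darker than background, signed
#'   difference), `"bright"`, or `"abs"` (unsigned).
#' @param weighted intensity-weighted centroid instead of the binary one.
#' @return list with `detected` (logical), `centroid_px` (named vector
#'   `x` = col, `y` = row, 0-based; `NA` if not detected), `area_px`,
#'   `threshold` used.
#' @export
segment_silhouette <- function(frame, background, roi,
                               min_area_px = 5, max_area_px = Inf,
                               threshold = NULL, min_contrast = 0.1,
                               polarity = c("dark", "bright", "abs"),
                               weighted = FALSE) {
  polarity <- polarity[1]
  if (!polarity %in% c("dark", "bright", "abs")) {
    stop("`polarity` must be one of \"dark\", \"bright\", \"abs\"", call. = FALSE)
  }
  r_lo <- max(1L, floor(roi$centre_row + 1 - roi$radius))
  r_hi <- min(nrow(frame), ceiling(roi$centre_row + 1 + roi$radius))
  c_lo <- max(1L, floor(roi$centre_col + 1 - roi$radius))
  c_hi <- min(ncol(frame), ceiling(roi$centre_col + 1 + roi$radius))
  sub <- background[r_lo:r_hi, c_lo:c_hi, drop = FALSE] -
    frame[r_lo:r_hi, c_lo:c_hi, drop = FALSE]
  sub <- switch(polarity,
                dark = pmax(sub, 0),
                bright = pmax(-sub, 0),
                abs = abs(sub))
  dy <- ((r_lo:r_hi) - 1) - roi$centre_row
  dx <- ((c_lo:c_hi) - 1) - roi$centre_col
  in_roi <- outer(dy^2, dx^2, `+`) <= roi$radius^2
  sub[!in_roi] <- 0

  no_detection <- list(detected = FALSE,
                       centroid_px = c(x = NA_real_, y = NA_real_),
                       area_px = 0L, threshold = threshold %||% NA_real_)
  if (max(sub) < min_contrast) return(no_detection)
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(sub, range = c(0, max(sub)))
  }
  lab <- EBImage::bwlabel(sub > threshold)
  if (max(lab) == 0) return(no_detection)
  areas <- tabulate(lab[lab > 0])
  ok <- which(areas >= min_area_px & areas <= max_area_px)
  if (length(ok) == 0) return(no_detection)
  comp <- ok[which.max(areas[ok])]
  px <- which(lab == comp, arr.ind = TRUE)
  w <- if (weighted) sub[lab == comp] else rep(1, nrow(px))
  list(detected = TRUE,
       centroid_px = c(x = sum((px[, 2] + c_lo - 2) * w) / sum(w),
                       y = sum((px[, 1] + r_lo - 2) * w) / sum(w)),
       area_px = areas[comp],
       threshold = threshold)
}

#' Track all dishes through a frame sequence
#'
#' Runs two-pass median background estimation (the second pass excludes a
#' disc around the first-pass fish detection, so slow-moving fish do not
#' imprint on the background) and silhouette segmentation per dish,
#' converts centroids to mm with the origin at the dish centre (x
#' rightwards, y downwards), linearly interpolates detection gaps of at
#' most `max_gap` frames (flagged `gap_filled`), and leaves longer gaps
#' invalid.
#'
#' @param frames list of greyscale matrices.
#' @param layout a [dish_layout()].
#' @param frame_rate frames per second (sets the timestamps).
#' @param max_gap longest detection gap (frames) to interpolate.
#' @param n_sample frames entering the background medians.
#' @param threshold fixed segmentation threshold; `NULL` (default)
#'   estimates one automatic threshold per dish (median Otsu over a few
#'   sampled frames) and reuses it for every frame.
#' @param ... further arguments to [segment_silhouette()].
#' @return a tibble (one row per dish x frame): `fish_id`, `dish_id`,
#'   `grid_label`, `frame` (0-based), `time_s`, `x_mm`, `y_mm`, `valid`,
#'   `gap_filled`.
#' @export
track_frames <- function(frames, layout, frame_rate, max_gap = 3,
                         n_sample = 101, threshold = NULL, ...) {
  px_per_mm <- attr(layout, "px_per_mm")
  n <- length(frames)
  out <- vector("list", nrow(layout))
  idx <- .bg_sample_idx(n, n_sample)
  for (d in seq_len(nrow(layout))) {
    # work on the dish bounding box only
    r_lo <- max(1L, floor(layout$centre_row_px[d] + 1 - layout$radius_px[d]))
    r_hi <- min(nrow(frames[[1]]), ceiling(layout$centre_row_px[d] + 1 + layout$radius_px[d]))
    c_lo <- max(1L, floor(layout$centre_col_px[d] + 1 - layout$radius_px[d]))
    c_hi <- min(ncol(frames[[1]]), ceiling(layout$centre_col_px[d] + 1 + layout$radius_px[d]))
    stack <- lapply(frames, function(f) f[r_lo:r_hi, c_lo:c_hi, drop = FALSE])
    roi <- list(centre_row = layout$centre_row_px[d] - (r_lo - 1),
                centre_col = layout$centre_col_px[d] - (c_lo - 1),
                radius = layout$radius_px[d])
    bg1 <- estimate_background(stack, n_sample)
    bg <- .refine_background(stack, bg1, roi, idx, threshold = threshold, ...)
    thr <- threshold
    if (is.null(thr)) {
      # one automatic threshold per dish, reused across frames
      cand <- vapply(stack[idx[seq(1, length(idx), length.out = min(5, length(idx)))]],
                     function(f) {
                       s <- segment_silhouette(f, bg, roi, ...)
                       if (is.na(s$threshold)) NA_real_ else s$threshold
                     }, numeric(1))
      if (any(is.finite(cand))) thr <- stats::median(cand, na.rm = TRUE)
    }
    xy <- matrix(NA_real_, n, 2)
    for (fi in seq_len(n)) {
      seg <- segment_silhouette(stack[[fi]], bg, roi, threshold = thr, ...)
      if (seg$detected) {
        xy[fi, ] <- seg$centroid_px + c(c_lo - 1, r_lo - 1)
      }
    }
    if (all(is.na(xy[, 1]))) {
      warning(sprintf("dish %d (%s): no detections; empty track",
                      layout$dish_id[d], layout$grid_label[d]))
    }
    filled <- .fill_gaps(xy, max_gap)
    out[[d]] <- tibble::tibble(
      fish_id = layout$dish_id[d],
      dish_id = layout$dish_id[d],
      grid_label = layout$grid_label[d],
      frame = seq_len(n) - 1L,
      time_s = (seq_len(n) - 1L) / frame_rate,
      x_mm = (filled$xy[, 1] - layout$centre_col_px[d]) / px_per_mm,
      y_mm = (filled$xy[, 2] - layout$centre_row_px[d]) / px_per_mm,
      valid = !is.na(filled$xy[, 1]),
      gap_filled = filled$gap_filled)
  }
  dplyr::bind_rows(out)
}

# linear interpolation of interior NA runs of length <= max_gap
.fill_gaps <- function(xy, max_gap) {
  n <- nrow(xy)
  gap_filled <- rep(FALSE, n)
  miss <- is.na(xy[, 1])
  if (any(miss) && any(!miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$lengths)) {
      if (!r$values[j] || r$lengths[j] > max_gap) next
      lo <- starts[j] - 1
      hi <- ends[j] + 1
      if (lo < 1 || hi > n) next # edge gaps are not extrapolated
      f <- (starts[j]:ends[j] - lo) / (hi - lo)
      xy[starts[j]:ends[j], 1] <- xy[lo, 1] + f * (xy[hi, 1] - xy[lo, 1])
      xy[starts[j]:ends[j], 2] <- xy[lo, 2] + f * (xy[hi, 2] - xy[lo, 2])
      gap_filled[starts[j]:ends[j]] <- TRUE
    }
  }
  list(xy = xy, gap_filled = gap_filled)
}
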