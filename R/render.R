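#' Render dorsal-view frame sequences from tracks
#'
#' Draws each fish as an ellipse-shaped silhouette centred on its true
#' centroid and oriented along the instantaneous heading, over a uniform
#' bright background (fish are filmed against back-lighting, so silhouettes
#' are dark), with optional additive Gaussian pixel noise. One fish per
#' dish; fish are assigned to dishes in order of their `fish_id`. The true
#' centroid of every fish in every frame is returned as ground truth for
#' validating the tracker.
#'
#' @param tracks long tibble with `fish_id`, `frame` (0-based), `x_mm`,
#'   `y_mm` (origin at the dish centre, x rightwards, y downwards). All fish
#'   must share the same frame set.
#' @param layout a [dish_layout()]; must have at least as many dishes as
#'   there are fish.
#' @param params a [render_params()].
#' @return a list of class `rendered_frames`:
#'   \describe{
#'     \item{frames}{list of greyscale matrices in `[0, 1]`, one per frame.}
#'     \item{truth}{tibble: `frame`, `fish_id`, `dish_id`, `row_px`,
#'       `col_px` (0-based true centroid).}
#'     \item{layout}{the layout.}
#'     \item{params}{the render parameters.}
#'   }
#' @export
render_frames <- function(tracks, layout, params = render_params()) {
  stopifnot(inherits(params, "render_params"))
  px_per_mm <- attr(layout, "px_per_mm")
  fish_ids <- sort(unique(tracks$fish_id))
  if (length(fish_ids) > nrow(layout)) {
    stop(sprintf("%d fish but only %d dishes in the layout",
                 length(fish_ids), nrow(layout)), call. = FALSE)
  }
  radius_mm <- attr(layout, "dish_diameter_mm") / 2
  bad <- which(sqrt(tracks$x_mm^2 + tracks$y_mm^2) +
                 params$fish_length_mm / 2 > radius_mm)
  if (length(bad) > 0) {
    stop(sprintf("track leaves the dish at frame %d (fish %s)",
                 tracks$frame[bad[1]], tracks$fish_id[bad[1]]), call. = FALSE)
  }

  nr <- attr(layout, "img_rows")
  nc <- attr(layout, "img_cols")
  a <- params$fish_length_mm / 2 * px_per_mm
  b <- a * params$fish_aspect

  # per-fish matrices of positions and headings, frames in order
  frames_idx <- sort(unique(tracks$frame))
  per_fish <- lapply(seq_along(fish_ids), function(i) {
    tr <- tracks[tracks$fish_id == fish_ids[i], ]
    tr <- tr[order(tr$frame), ]
    if (!identical(tr$frame, frames_idx)) {
      stop("all fish must cover the same frame set", call. = FALSE)
    }
    dx <- c(diff(tr$x_mm), 0)
    dy <- c(diff(tr$y_mm), 0)
    th <- atan2(dy, dx)
    still <- dx == 0 & dy == 0
    # stationary frames keep the last moving heading
    if (all(still)) th[] <- 0 else {
      for (k in seq_along(th)) if (still[k] && k > 1) th[k] <- th[k - 1]
      if (still[1]) th[1] <- th[which(!still)[1]]
    }
    list(dish = layout[i, ], x = tr$x_mm, y = tr$y_mm, theta = th)
  })

  frames <- vector("list", length(frames_idx))
  truth <- vector("list", length(frames_idx))
  for (fi in seq_along(frames_idx)) {
    img <- matrix(params$background_grey, nr, nc)
    tr_rows <- vector("list", length(per_fish))
    for (i in seq_along(per_fish)) {
      pf <- per_fish[[i]]
      # 0-based pixel position of the centroid
      cr <- pf$dish$centre_row_px + pf$y[fi] * px_per_mm
      cc <- pf$dish$centre_col_px + pf$x[fi] * px_per_mm
      img <- .draw_ellipse(img, cr, cc, a, b, pf$theta[fi], params$fish_grey)
      tr_rows[[i]] <- tibble::tibble(frame = frames_idx[fi],
                                     fish_id = fish_ids[i],
                                     dish_id = pf$dish$dish_id,
                                     row_px = cr, col_px = cc)
    }
    if (params$pixel_noise_sd > 0) {
      set.seed(derive_seed(params$seed, "render", frames_idx[fi]))
      img <- img + matrix(stats::rnorm(nr * nc, 0, params$pixel_noise_sd), nr, nc)
      img[img < 0] <- 0
      img[img > 1] <- 1
    }
    frames[[fi]] <- img
    truth[[fi]] <- dplyr::bind_rows(tr_rows)
  }
  structure(list(frames = frames, truth = dplyr::bind_rows(truth),
                 layout = layout, params = params),
            class = "rendered_frames")
}

# paint the filled ellipse (centre 0-based px, semi-axes a >= b, rotation
# theta) onto img; a pixel is inside if its centre satisfies the ellipse
# inequality
.draw_ellipse <- function(img, cr, cc, a, b, theta, grey) {
  r_lo <- max(1L, floor(cr + 1 - a))
  r_hi <- min(nrow(img), ceiling(cr + 1 + a))
  c_lo <- max(1L, floor(cc + 1 - a))
  c_hi <- min(ncol(img), ceiling(cc + 1 + a))
  rows <- r_lo:r_hi
  cols <- c_lo:c_hi
  dy <- (rows - 1) - cr              # pixel centre row (0-based) minus centroid
  dx <- (cols - 1) - cc
  ct <- cos(theta); st <- sin(theta)
  # x along heading (col direction is x, row direction is y)
  xr <- outer(dy, dx, function(y, x)  x * ct + y * st)
  yr <- outer(dy, dx, function(y, x) -x * st + y * ct)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  sub <- img[rows, cols, drop = FALSE]
  sub[inside] <- grey
  img[rows, cols] <- sub
  img
}

#' Write / read a rendered frame sequence
#'
#' Frames go to `frame_%04d.png` (8-bit greyscale) plus a `layout.csv`
#' ([write_layout()]) and `truth.csv` in the same directory.
#'
#' @param rendered a [render_frames()] result.
#' @param dir output directory (created if needed).
#' @return `write_frames` returns `dir` invisibly; `read_frames` returns a
#'   list with `frames` (list of matrices) and `layout`.
#' @export
write_frames <- function(rendered, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(rendered$frames)) {
    png::writePNG(rendered$frames[[i]],
                  file.path(dir, sprintf("frame_%04d.png", i - 1)))
  }
  write_layout(rendered$layout, file.path(dir, "layout.csv"))
  utils::write.csv(rendered$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no frame PNGs found in ", dir, call. = FALSE)
  list(frames = lapply(files, png::readPNG),
       layout = read_layout(file.path(dir, "layout.csv")))
}
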