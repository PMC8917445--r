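#' Build a Petri-dish array layout
#'
#' The two filming arrangements are a 3x3 array of 55 mm dishes (feeding
#' assay, up to 9 fish) and a 1x5 row of 35 mm dishes (fast-start assay, up
#' to 5 fish). Pixel coordinates are 0-based with row increasing downwards.
#'
#' @param pattern `"3x3"` or `"1x5"`.
#' @param dish_diameter_mm dish diameter; defaults to 55 mm for `"3x3"` and
#'   35 mm for `"1x5"`.
#' @param px_per_mm imaging scale.
#' @param margin_mm clearance between dish rims and between rim and image
#'   border.
#' @return a tibble of class `dish_layout` with one row per dish
#'   (`dish_id`, `grid_label`, `centre_row_px`, `centre_col_px`,
#'   `radius_px`) and attributes `px_per_mm`, `dish_diameter_mm`,
#'   `img_rows`, `img_cols`.
#' @export
dish_layout <- function(pattern = c("3x3", "1x5"),
                        dish_diameter_mm = NULL,
                        px_per_mm = 4,
                        margin_mm = 4) {
  pattern <- match.arg(pattern)
  dims <- if (pattern == "3x3") c(3L, 3L) else c(1L, 5L)
  if (is.null(dish_diameter_mm)) {
    dish_diameter_mm <- if (pattern == "3x3") 55 else 35
  }
  assert_pos(dish_diameter_mm, "dish_diameter_mm")
  assert_pos(px_per_mm, "px_per_mm")

  pitch <- dish_diameter_mm + margin_mm
  radius_px <- dish_diameter_mm / 2 * px_per_mm
  centre_mm <- function(k) margin_mm + dish_diameter_mm / 2 + (k - 1) * pitch
  grid <- expand.grid(col = seq_len(dims[2]), row = seq_len(dims[1]))

  layout <- tibble::tibble(
    dish_id = seq_len(nrow(grid)),
    grid_label = if (pattern == "1x5") paste0("P", grid$col)
                 else paste0("r", grid$row, "c", grid$col),
    centre_row_px = centre_mm(grid$row) * px_per_mm,
    centre_col_px = centre_mm(grid$col) * px_per_mm,
    radius_px = radius_px)
  structure(layout,
            class = c("dish_layout", class(layout)),
            px_per_mm = px_per_mm,
            dish_diameter_mm = dish_diameter_mm,
            img_rows = ceiling((margin_mm + dims[1] * pitch) * px_per_mm),
            img_cols = ceiling((margin_mm + dims[2] * pitch) * px_per_mm))
}

#' Calibrate the pixel-to-mm scale from a dish layout
#'
#' Each dish implies a scale of `2 * radius_px / diameter_mm`; the scales
#' must agree across dishes (coefficient of variation < 5%), otherwise the
#' layout mixes imaging scales and calibration fails, naming the offending
#' dishes.
#'
#' @param layout a [dish_layout()] (or a data frame with `radius_px` and
#'   either a `dish_diameter_mm` column or attribute).
#' @return the scale in px/mm (mean across dishes).
#' @export
calibrate_scale <- function(layout) {
  diam <- layout[["dish_diameter_mm"]] %||% attr(layout, "dish_diameter_mm")
  if (is.null(diam)) stop("layout carries no dish diameter", call. = FALSE)
  scales <- 2 * layout$radius_px / diam
  if (length(scales) > 1) {
    cv <- stats::sd(scales) / mean(scales)
    if (is.finite(cv) && cv >= 0.05) {
      off <- layout$dish_id[abs(scales - stats::median(scales)) >
                              0.05 * stats::median(scales)]
      stop(sprintf("inconsistent px/mm scales across dishes (CV = %.1f%%); offending dishes: %s",
                   100 * cv, paste(off, collapse = ", ")), call. = FALSE)
    }
  }
  mean(scales)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a dish-layout file
#'
#' Plain-text CSV with one row per dish plus the image-level constants
#' repeated per row, so the file is self-contained.
#'
#' @param layout a [dish_layout()].
#' @param path file path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns a
#'   `dish_layout`.
#' @export
write_layout <- function(layout, path) {
  df <- as.data.frame(layout)
  df$px_per_mm <- attr(layout, "px_per_mm")
  df$dish_diameter_mm <- attr(layout, "dish_diameter_mm")
  df$img_rows <- attr(layout, "img_rows")
  df$img_cols <- attr(layout, "img_cols")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path)
  layout <- tibble::as_tibble(df[c("dish_id", "grid_label", "centre_row_px",
                                   "centre_col_px", "radius_px")])
  structure(layout,
            class = c("dish_layout", class(layout)),
            px_per_mm = df$px_per_mm[1],
            dish_diameter_mm = df$dish_diameter_mm[1],
            img_rows = df$img_rows[1],
            img_cols = df$img_cols[1])
}
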