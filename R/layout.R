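#' Plug-tray layout
#'
#' Describes the tray geometry: the grid of cells, the rectangle of the image
#' the tray occupies, and the pixel-to-area scale
#' `scale_k = actual_tray_area / number of tray pixels` (mm^2 per pixel) used
#' to convert leaf pixel counts to physical leaf area. The default is the
#' 21-cell tray used throughout: 3 rows by 7 columns.
#'
#' When the tray width/height is not divisible by the number of
#' columns/rows, the rightmost/bottom cells absorb the remainder pixels, so
#' cells tile the region exactly.
#'
#' @param n_rows,n_cols Cell grid dimensions.
#' @param region Tray rectangle in image coordinates:
#'   `c(row, col, height, width)` of the top-left pixel (1-based) and pixel
#'   extent.
#' @param actual_tray_area Physical tray area in mm^2. The default
#'   (540 x 280 mm) is a common 21-cell nursery tray.
#' @return A `tray_layout` list with `scale_k` filled in.
#' @export
tray_layout <- function(n_rows = 3L, n_cols = 7L,
                        region = c(row = 1L, col = 1L, height = 144L, width = 336L),
                        actual_tray_area = 540 * 280) {
  if (!is_scalar_number(n_rows) || !is_scalar_number(n_cols) ||
    n_rows < 1 || n_cols < 1) {
    abort("`n_rows` and `n_cols` must be positive integers.")
  }
  region <- as.integer(region)
  if (length(region) != 4L || any(region[3:4] < 1L)) {
    abort("`region` must be c(row, col, height, width) with positive extent.")
  }
  if (region[3] < n_rows || region[4] < n_cols) {
    abort("Tray region is smaller than the cell grid.")
  }
  names(region) <- c("row", "col", "height", "width")
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      region = region,
      actual_tray_area = actual_tray_area,
      scale_k = actual_tray_area / (region[["height"]] * region[["width"]])
    ),
    class = "tray_layout"
  )
}

#' Cell rectangles of a tray layout
#'
#' @param layout A [tray_layout()].
#' @return A tibble with one row per cell: `row`, `col`, pixel bounds
#'   `r0`/`r1`/`c0`/`c1` (inclusive, image coordinates) and `cell_px`.
#' @export
cell_rects <- function(layout) {
  if (!inherits(layout, "tray_layout")) {
    abort("`layout` must be created with `tray_layout()`.")
  }
  reg <- layout$region
  rb <- cell_breaks(reg[["row"]], reg[["height"]], layout$n_rows)
  cb <- cell_breaks(reg[["col"]], reg[["width"]], layout$n_cols)
  grid <- tidyr::expand_grid(row = seq_len(layout$n_rows), col = seq_len(layout$n_cols))
  dplyr::mutate(grid,
    r0 = rb$lo[.data$row], r1 = rb$hi[.data$row],
    c0 = cb$lo[.data$col], c1 = cb$hi[.data$col],
    cell_px = (.data$r1 - .data$r0 + 1L) * (.data$c1 - .data$c0 + 1L)
  )
}

# Split `extent` pixels starting at `start` into `n` runs; the last run
# absorbs the integer-division remainder.
cell_breaks <- function(start, extent, n) {
  base <- extent %/% n
  sizes <- rep(base, n)
  sizes[n] <- sizes[n] + extent %% n
  hi <- start - 1L + cumsum(sizes)
  lo <- hi - sizes + 1L
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Tray-cell output coordinates
#'
#' Converts 1-based cell indices to the coordinate convention used for
#' transplanter output: the origin is the upper-left corner of the tray
#' image, X increases rightward and Y downward, and cell centers sit on the
#' odd lattice `x = 2 col - 1`, `y = 2 row - 1`. For the 7-column, 3-row tray
#' this yields x in {1, 3, ..., 13} and y in {1, 3, 5}.
#'
#' @param row,col Cell indices (vectors allowed), 1-based.
#' @param layout A [tray_layout()] used for range checking.
#' @return A tibble with columns `x` and `y`.
#' @examples
#' cell_coordinate(2, 7) # x = 13, y = 3
#' @export
cell_coordinate <- function(row, col, layout = tray_layout()) {
  if (length(row) != length(col)) {
    abort("`row` and `col` must have the same length.")
  }
  if (any(row < 1 | row > layout$n_rows) || any(col < 1 | col > layout$n_cols)) {
    abort("Cell index out of range for this layout.")
  }
  tibble(x = 2L * as.integer(col) - 1L, y = 2L * as.integer(row) - 1L)
}
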