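#' Count leaf pixels per tray cell
#'
#' Splits the tray region of a segmented 0/1 mask into its cell rectangles
#' and counts the foreground (leaf) pixels in each. Every foreground pixel
#' inside the tray region is counted exactly once; pixels of leaves crossing
#' a cell border are attributed to the cell that contains them.
#'
#' @param mask An integer 0/1 matrix covering the tray region.
#' @param layout A [tray_layout()].
#' @return A tibble with `row`, `col`, `pixel_count` and `cell_px`.
#' @export
partition_cells <- function(mask, layout = tray_layout()) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L))) {
    abort("`mask` must be a 0/1 matrix.")
  }
  reg <- layout$region
  if (reg[["row"]] + reg[["height"]] - 1L > nrow(mask) ||
    reg[["col"]] + reg[["width"]] - 1L > ncol(mask)) {
    abort("Tray region extends outside the mask.")
  }
  rects <- cell_rects(layout)
  counts <- purrr::pmap_int(
    rects[c("r0", "r1", "c0", "c1")],
    function(r0, r1, c0, c1) sum(mask[r0:r1, c0:c1])
  )
  dplyr::mutate(
    rects[c("row", "col", "cell_px")],
    pixel_count = counts,
    .before = "cell_px"
  )
}

#' Leaf area from a pixel count
#'
#' Converts a leaf pixel count `P` to physical leaf area `M = K * P`, where
#' `K` is the layout's mm^2-per-pixel scale (the ratio of the physical tray
#' area to the number of tray pixels).
#'
#' @param pixel_count Leaf pixel count(s), non-negative.
#' @param layout A [tray_layout()] supplying `scale_k`.
#' @return Leaf area in mm^2.
#' @export
leaf_area <- function(pixel_count, layout = tray_layout()) {
  if (any(pixel_count < 0)) {
    abort("`pixel_count` must be non-negative.")
  }
  layout$scale_k * pixel_count
}

#' Leaf-cover ratio of a cell
#'
#' The grading statistic `F`: the leaf area of a cell's plant divided by the
#' cell's area. Since both are measured in pixels of the same image, the
#' physical scale cancels and `F = pixel_count / cell_pixels`. `F` can exceed
#' 1 only if leaves from neighboring cells cross into the cell; the raw value
#' is reported.
#'
#' @param pixel_count Leaf pixel count(s) in the cell.
#' @param cell_pixels Total pixel area of the cell (> 0).
#' @return The dimensionless ratio `F`.
#' @export
area_ratio <- function(pixel_count, cell_pixels) {
  if (any(cell_pixels <= 0)) {
    abort("`cell_pixels` must be positive.")
  }
  if (any(pixel_count < 0)) {
    abort("`pixel_count` must be non-negative.")
  }
  pixel_count / cell_pixels
}

#' Grading thresholds on the leaf-cover ratio
#'
#' The four-class grading of a cell by its leaf-cover ratio `F` uses three
#' thresholds: the calibrated group-average `f_avg`, the calibrated minimum
#' `f_min`, and the empty-cell bound `f_empty`. Defaults are the calibrated
#' pepper-seedling values 0.20 / 0.16 / 0.015.
#'
#' @param f_avg Healthy bound: `F > f_avg` is healthy.
#' @param f_min Sub-healthy lower bound: `f_min <= F <= f_avg` is
#'   sub-healthy.
#' @param f_empty Empty-cell bound: `F < f_empty` is an empty cell; between
#'   `f_empty` and `f_min` the cell holds a poor-quality seedling.
#' @return A `class_thresholds` list.
#' @export
class_thresholds <- function(f_avg = 0.20, f_min = 0.16, f_empty = 0.015) {
  if (!(f_empty < f_min && f_min < f_avg)) {
    abort("Thresholds must satisfy f_empty < f_min < f_avg.")
  }
  structure(
    list(f_avg = f_avg, f_min = f_min, f_empty = f_empty),
    class = "class_thresholds"
  )
}

seedling_labels <- c("empty", "poor", "sub_healthy", "healthy")

#' Classify a cell by its leaf-cover ratio
#'
#' Four-class grading: `empty` if `F < f_empty`; otherwise `healthy` if
#' `F > f_avg`; `sub_healthy` if `f_min <= F <= f_avg` (both ends inclusive);
#' `poor` otherwise. The result is an ordered factor
#' `empty < poor < sub_healthy < healthy`, and the rule is monotone in `F`.
#'
#' @param f Leaf-cover ratio(s), non-negative.
#' @param thresholds A [class_thresholds()].
#' @return An ordered factor with levels empty, poor, sub_healthy, healthy.
#' @examples
#' classify_seedling(c(0.22, 0.18, 0.10, 0.01))
#' @export
classify_seedling <- function(f, thresholds = class_thresholds()) {
  if (any(f < 0) || anyNA(f)) {
    abort("`f` must be non-negative.")
  }
  out <- ifelse(f < thresholds$f_empty, "empty",
    ifelse(f > thresholds$f_avg, "healthy",
      ifelse(f >= thresholds$f_min, "sub_healthy", "poor")
    )
  )
  factor(out, levels = seedling_labels, ordered = TRUE)
}

#' Calibrate grading thresholds from measured leaf-cover ratios
#'
#' Summarizes groups of measured `F` ratios into per-group maximum, mean and
#' minimum, and pools them: the pooled `f_avg` is the mean of the group
#' means, the pooled `f_max` the largest group maximum, and the pooled
#' `f_min` the smallest group minimum. Per-group statistics are reported at
#' two decimals, matching field practice; pooling is computed from the
#' reported per-group values.
#'
#' @param data Either a tibble of raw measurements with columns `group` and
#'   `f`, or a tibble of per-group summaries with columns `group`, `f_max`,
#'   `f_avg`, `f_min` (e.g. [pepper_threshold_groups()]).
#' @return An `f_calibration` list with tibbles `per_group` and `pooled`.
#' @examples
#' calibrate_thresholds(pepper_threshold_groups())$pooled
#' @export
calibrate_thresholds <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.")
  }
  if (all(c("group", "f") %in% names(data))) {
    if (anyNA(data$f)) {
      abort("Missing F values.")
    }
    per_group <- dplyr::summarise(
      dplyr::group_by(data, .data$group),
      f_max = round(max(.data$f), 2),
      f_avg = round(mean(.data$f), 2),
      f_min = round(min(.data$f), 2),
      n = dplyr::n(),
      .groups = "drop"
    )
    if (any(per_group$n == 0)) {
      abort("Every group must be non-empty.")
    }
  } else if (all(c("group", "f_max", "f_avg", "f_min") %in% names(data))) {
    if (nrow(data) == 0) {
      abort("Every group must be non-empty.")
    }
    per_group <- as_tibble(data[c("group", "f_max", "f_avg", "f_min")])
  } else {
    abort("`data` needs columns (group, f) or (group, f_max, f_avg, f_min).")
  }
  pooled <- tibble(
    f_max = max(per_group$f_max),
    f_avg = round(mean(per_group$f_avg), 2),
    f_min = min(per_group$f_min)
  )
  structure(list(per_group = per_group, pooled = pooled), class = "f_calibration")
}

#' @export
print.f_calibration <- function(x, ...) {
  cat("<f_calibration>\n")
  cat(sprintf(
    "  pooled: f_max = %.2f, f_avg = %.2f, f_min = %.2f (%d groups)\n",
    x$pooled$f_max, x$pooled$f_avg, x$pooled$f_min, nrow(x$per_group)
  ))
  invisible(x)
}

#' Healthy-seedling identification accuracy
#'
#' Per-group accuracy of healthy-seedling identification:
#' `100 * identified_healthy / actual_healthy`, reported at two decimals, and
#' the arithmetic mean of the per-group accuracies. If a `method` column is
#' present, accuracies are computed per method.
#'
#' @param data A tibble with columns `group`, `actual_healthy`,
#'   `identified_healthy`, and optionally `method`.
#' @return A list with tibbles `per_group` (accuracy per group) and
#'   `average` (mean accuracy, one row per method).
#' @examples
#' evaluate_accuracy(tibble::tibble(
#'   group = c("A", "B", "C"),
#'   actual_healthy = c(75, 94, 72),
#'   identified_healthy = c(72, 87, 68)
#' ))
#' @export
evaluate_accuracy <- function(data) {
  need <- c("group", "actual_healthy", "identified_healthy")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort("`data` needs columns group, actual_healthy, identified_healthy.")
  }
  if (any(data$actual_healthy <= 0)) {
    abort("Accuracy is undefined for groups with no actual healthy seedlings.")
  }
  if (!"method" %in% names(data)) {
    data$method <- "proposed"
  }
  per_group <- dplyr::mutate(
    as_tibble(data[c("method", "group", "actual_healthy", "identified_healthy")]),
    accuracy = round(100 * .data$identified_healthy / .data$actual_healthy, 2)
  )
  average <- dplyr::summarise(
    dplyr::group_by(per_group, .data$method),
    average_accuracy = round(mean(100 * .data$identified_healthy / .data$actual_healthy), 2),
    .groups = "drop"
  )
  list(per_group = per_group, average = average)
}
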