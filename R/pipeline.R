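#' Full identification pipeline configuration
#'
#' Bundles the per-stage settings of the end-to-end pipeline: color index,
#' threshold search, binarization reading, mask denoising, tray geometry and
#' grading thresholds. A single `seed` drives the only stochastic stage (the
#' genetic algorithm) unless the GA config carries its own seed.
#'
#' The pipeline default binarization is `upper_class` (leaf = top entropy
#' class): under the green index the scene materials order
#' tray < substrate < leaf, so only the top class measures leaf area. The
#' literal `geq_min` rule remains available for single-threshold scenes.
#'
#' @param index `"tg"` (default), `"tr"` or `"gray"` — the preprocessing
#'   transform fed to segmentation.
#' @param binarize_mode Passed to [binarize()]; default `"upper_class"`.
#' @param denoise_first If `TRUE`, BM3D runs on the quantized gray image
#'   before thresholding; the default (`FALSE`) denoises the binary mask
#'   after thresholding and re-binarizes at 0.5, which also fills small leaf
#'   holes.
#' @param ga A [ga_config()].
#' @param bm3d A [bm3d_config()].
#' @param layout A [tray_layout()].
#' @param thresholds A [class_thresholds()].
#' @param denoise Apply BM3D at all? Default `TRUE`.
#' @param seed Integer seed for the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(index = c("tg", "tr", "gray"),
                            binarize_mode = c("upper_class", "geq_min", "band"),
                            denoise_first = FALSE,
                            ga = ga_config(),
                            bm3d = bm3d_config(),
                            layout = tray_layout(),
                            thresholds = class_thresholds(),
                            denoise = TRUE,
                            seed = NULL) {
  index <- match.arg(index)
  binarize_mode <- match.arg(binarize_mode)
  stopifnot(
    inherits(ga, "ga_config"), inherits(bm3d, "bm3d_config"),
    inherits(layout, "tray_layout"), inherits(thresholds, "class_thresholds")
  )
  structure(
    list(
      index = index, binarize_mode = binarize_mode,
      denoise_first = denoise_first, denoise = denoise,
      ga = ga, bm3d = bm3d, layout = layout, thresholds = thresholds,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Identify and grade every seedling in a tray image
#'
#' Runs the full identification pipeline on an RGB tray image: color-index
#' preprocessing, quantization, genetic-algorithm maximum-entropy
#' two-threshold segmentation, BM3D mask denoising, per-cell leaf pixel
#' counting, leaf-area conversion, four-class grading on the leaf-cover
#' ratio `F`, and tray-cell coordinates for the transplanter. Deterministic
#' for a fixed seed.
#'
#' @param image An `H x W x 3` RGB array in `[0, 255]` (see
#'   [read_tray_image()]).
#' @param config A [pipeline_config()].
#' @return A `tray_result` with:
#' \describe{
#'   \item{records}{tibble, one row per cell: `row`, `col`, `x`, `y`,
#'     `pixel_count`, `leaf_area_mm2`, `f`, `label` (with `f` and
#'     `leaf_area_mm2` reported at two decimals in exports; raw values are
#'     kept here).}
#'   \item{t1, t2, ga}{the selected thresholds and the underlying `ga_fit`.}
#'   \item{mask}{the final 0/1 leaf mask.}
#' }
#' Supports [tidy()], [glance()], [summary()] and [autoplot()].
#' @examples
#' tray <- generate_tray(synth_spec(per_cell_f = 0.3, seed = 1))
#' res <- run_pipeline(tray$image, pipeline_config(seed = 1))
#' glance(res)
#' @export
run_pipeline <- function(image, config = pipeline_config()) {
  assert_rgb_image(image)
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created with `pipeline_config()`.")
  }
  ga_cfg <- config$ga
  if (is.null(ga_cfg$seed)) {
    ga_cfg$seed <- config$seed
  }

  gray_raw <- switch(config$index,
    tg = color_index(image, "tg"),
    tr = color_index(image, "tr"),
    gray = to_grayscale(image)
  )
  gray <- quantize_gray(gray_raw)

  if (config$denoise && config$denoise_first) {
    den <- bm3d_denoise(gray, config$bm3d)
    gray <- quantize_gray(den$estimate)
  }

  hist <- intensity_histogram(gray)
  fit <- ga_thresholds(hist, ga_cfg)
  mask <- binarize(gray, fit$t1, fit$t2, config$binarize_mode)

  if (config$denoise && !config$denoise_first) {
    den <- bm3d_denoise(mask * 1.0, config$bm3d)
    mask <- matrix(as.integer(den$estimate >= 0.5), nrow = nrow(mask))
  }

  records <- partition_cells(mask, config$layout)
  records <- dplyr::mutate(records,
    leaf_area_mm2 = leaf_area(.data$pixel_count, config$layout),
    f = area_ratio(.data$pixel_count, .data$cell_px),
    label = classify_seedling(.data$f, config$thresholds)
  )
  coords <- cell_coordinate(records$row, records$col, config$layout)
  records <- dplyr::relocate(
    dplyr::mutate(records, x = coords$x, y = coords$y),
    "row", "col", "x", "y", "pixel_count", "leaf_area_mm2", "f", "label"
  )

  structure(
    list(
      records = records,
      t1 = fit$t1, t2 = fit$t2, ga = fit,
      mask = mask, config = config
    ),
    class = "tray_result"
  )
}

#' @export
print.tray_result <- function(x, ...) {
  counts <- table(x$records$label)
  cat(sprintf(
    "<tray_result> %d cells | thresholds (t1, t2) = (%d, %d)\n",
    nrow(x$records), x$t1, x$t2
  ))
  cat(sprintf(
    "  healthy %d | sub_healthy %d | poor %d | empty %d\n",
    counts[["healthy"]], counts[["sub_healthy"]], counts[["poor"]], counts[["empty"]]
  ))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object A `tray_result`.
#' @param ... Unused.
#' @method tidy tray_result
#' @export
tidy.tray_result <- function(x, ...) {
  x$records
}

#' @rdname run_pipeline
#' @method glance tray_result
#' @export
glance.tray_result <- function(x, ...) {
  counts <- table(x$records$label)
  tibble(
    n_cells = nrow(x$records),
    healthy = counts[["healthy"]],
    sub_healthy = counts[["sub_healthy"]],
    poor = counts[["poor"]],
    empty = counts[["empty"]],
    t1 = x$t1, t2 = x$t2,
    ga_fitness = x$ga$fitness,
    ga_generations = x$ga$generations
  )
}

#' @rdname run_pipeline
#' @export
summary.tray_result <- function(object, ...) {
  recs <- object$records
  by_label <- split(recs, recs$label)
  coords <- lapply(by_label, function(d) {
    if (nrow(d) == 0) {
      return(character(0))
    }
    sprintf("(%d,%d)", d$x, d$y)
  })
  structure(
    list(counts = vapply(by_label, nrow, integer(1)), coordinates = coords),
    class = "summary.tray_result"
  )
}

#' @export
print.summary.tray_result <- function(x, ...) {
  for (lab in rev(names(x$counts))) {
    cat(sprintf(
      "%-12s %2d  %s\n", lab, x$counts[[lab]],
      paste(x$coordinates[[lab]], collapse = " ")
    ))
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @method autoplot tray_result
#' @export
autoplot.tray_result <- function(object, ...) {
  recs <- object$records
  ggplot2::ggplot(recs, ggplot2::aes(.data$x, .data$y, fill = .data$label)) +
    ggplot2::geom_tile(colour = "grey30", width = 1.8, height = 1.8) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$f)), size = 3) +
    ggplot2::scale_y_reverse(breaks = unique(recs$y)) +
    ggplot2::scale_x_continuous(breaks = unique(recs$x)) +
    ggplot2::scale_fill_manual(values = c(
      healthy = "#4daf4a", sub_healthy = "#ffff99",
      poor = "#ff7f00", empty = "grey80"
    ), drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "X (rightward)", y = "Y (downward)", fill = "Grade",
      title = "Tray grading (cell leaf-cover ratio F)"
    ) +
    ggplot2::theme_minimal()
}
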