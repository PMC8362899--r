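#' Calibration measurements for 20 groups of pepper seedlings
#'
#' Per-group maximum, mean and minimum leaf-cover ratio `F` measured on 20
#' groups of pepper seedlings (2,100 plants in total), used to calibrate the
#' grading thresholds. The values are stored exactly as recorded; note that
#' group 18 reports a minimum of 0.15, below the 0.16 used as the default
#' `f_min` (which follows the pooled calibration summary).
#'
#' @return A tibble with columns `group`, `f_max`, `f_avg`, `f_min`.
#' @seealso [calibrate_thresholds()]
#' @export
pepper_threshold_groups <- function() {
  path <- system.file("extdata", "pepper_threshold_groups.csv", package = "plugtray")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Validation counts for three groups of pepper seedling trays
#'
#' Class counts (healthy, sub-healthy, poor, empty) for three validation
#' groups of pepper seedling trays: the actual composition, the counts
#' identified by this pipeline, and the counts identified by a comparison
#' leaf-area method (consumed as given numbers).
#'
#' @return A tibble with columns `group`, `method` (actual / proposed /
#'   comparison), `healthy`, `sub_healthy`, `poor`, `empty`.
#' @seealso [evaluate_accuracy()]
#' @export
pepper_group_counts <- function() {
  path <- system.file("extdata", "pepper_group_counts.csv", package = "plugtray")
  readr::read_csv(path, show_col_types = FALSE)
}
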