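#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file into a [pipeline_config()]. Missing fields take the
#' documented defaults (an empty file yields the full default configuration);
#' unknown keys are rejected so typos fail loudly; invalid values (e.g.
#' grading thresholds out of order) raise the same errors as the
#' constructors.
#'
#' Recognized top-level keys: `index`, `binarize_mode`, `denoise`,
#' `denoise_first`, `seed`, and the sections `ga`, `bm3d`, `layout`,
#' `thresholds`, `output` (paths `csv`, `json`, `mask`).
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`; any `output` section is attached as
#'   `attr(, "output")`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) {
    raw <- list()
  }
  known <- c(
    "index", "binarize_mode", "denoise", "denoise_first", "seed",
    "ga", "bm3d", "layout", "thresholds", "output"
  )
  check_keys(raw, known, "top level")

  ga <- build_from(raw$ga, ga_config, "ga")
  bm3d <- build_from(raw$bm3d, bm3d_config, "bm3d")
  layout <- build_layout(raw$layout)
  thresholds <- build_from(raw$thresholds, class_thresholds, "thresholds")

  args <- list(ga = ga, bm3d = bm3d, layout = layout, thresholds = thresholds)
  for (k in c("index", "binarize_mode", "denoise", "denoise_first", "seed")) {
    if (!is.null(raw[[k]])) {
      args[[k]] <- raw[[k]]
    }
  }
  cfg <- do.call(pipeline_config, args)
  if (!is.null(raw$output)) {
    check_keys(raw$output, c("csv", "json", "mask"), "output")
    attr(cfg, "output") <- raw$output
  }
  cfg
}

check_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    abort(sprintf(
      "Unknown config key(s) at %s: %s", where, paste(extra, collapse = ", ")
    ))
  }
}

build_from <- function(section, constructor, where) {
  if (is.null(section)) {
    return(constructor())
  }
  check_keys(section, names(formals(constructor)), where)
  do.call(constructor, section)
}

build_layout <- function(section) {
  if (is.null(section)) {
    return(tray_layout())
  }
  check_keys(section, names(formals(tray_layout)), "layout")
  if (!is.null(section$region)) {
    section$region <- unlist(section$region)
  }
  do.call(tray_layout, section)
}

#' Write pipeline results to CSV and JSON
#'
#' Serializes a [run_pipeline()] result: a per-cell CSV (columns `row`,
#' `col`, `x`, `y`, `pixel_count`, `leaf_area_mm2`, `f`, `label`, with `f`
#' and the area reported at two decimals) and a JSON summary carrying class
#' counts, the coordinate list of each grade, and the segmentation
#' thresholds. Files are written atomically (temp file + rename), and a rerun
#' on identical inputs is byte-identical. With no records, a header-only CSV
#' is written and a warning raised.
#'
#' @param result A `tray_result`.
#' @param csv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
emit_results <- function(result, csv = NULL, json = NULL) {
  if (!inherits(result, "tray_result")) {
    abort("`result` must come from `run_pipeline()`.")
  }
  recs <- dplyr::mutate(result$records,
    leaf_area_mm2 = round(.data$leaf_area_mm2, 2),
    f = round(.data$f, 2),
    label = as.character(.data$label)
  )
  recs <- recs[c("row", "col", "x", "y", "pixel_count", "leaf_area_mm2", "f", "label")]
  if (nrow(recs) == 0) {
    warn("No cell records; writing a header-only CSV.")
  }
  written <- character(0)
  if (!is.null(csv)) {
    tmp <- tempfile(tmpdir = dirname(csv), fileext = ".csv")
    readr::write_csv(recs, tmp)
    file.rename(tmp, csv)
    written <- c(written, csv)
  }
  if (!is.null(json)) {
    s <- summary(result)
    payload <- list(
      n_cells = nrow(result$records),
      counts = as.list(s$counts),
      coordinates = s$coordinates,
      thresholds = list(
        t1 = result$t1, t2 = result$t2,
        fitness = round(result$ga$fitness, 6),
        generations = result$ga$generations
      )
    )
    tmp <- tempfile(tmpdir = dirname(json), fileext = ".json")
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    file.rename(tmp, json)
    written <- c(written, json)
  }
  invisible(written)
}
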