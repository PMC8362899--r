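#' Read a tray image into an 8-bit RGB array
#'
#' Reads a PNG, TIFF or JPEG raster and normalizes it to the package's image
#' container: an `H x W x 3` numeric array with channels in R, G, B order and
#' integer values in `[0, 255]`. Grayscale sources are replicated across the
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG, TIFF or JPEG file (8-bit per channel).
#' @return An `H x W x 3` array of integers in `[0, 255]`.
#' @examples
#' img <- generate_tray(synth_spec(seed = 1))$image
#' tf <- tempfile(fileext = ".png")
#' write_mask(img / 255, tf)
#' dim(read_tray_image(tf))
#' @export
read_tray_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Image file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("Reading TIFF images requires the 'tiff' package.")
      }
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        abort("Reading JPEG images requires the 'jpeg' package.")
      }
      jpeg::readJPEG(path)
    },
    abort(sprintf("Unsupported image format '.%s' (use PNG, TIFF or JPEG).", ext))
  )
  if (is.matrix(raw)) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  }
  if (length(dim(raw)) == 3L && dim(raw)[3] >= 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (length(dim(raw)) != 3L) {
    abort(sprintf("Unexpected image shape in %s", path))
  }
  img <- round_half_up(raw * 255)
  storage.mode(img) <- "double"
  assert_rgb_image(img, "image")
}

#' Write a mask or image as PNG
#'
#' Writes a binary mask (0/1 matrix), a gray image, or an RGB array to a PNG
#' file. Matrices are interpreted on a `[0, 1]` scale if their maximum is at
#' most 1, otherwise on `[0, 255]`; RGB arrays are always on `[0, 255]`.
#'
#' @param x A 0/1 matrix, gray matrix, or `H x W x 3` array.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(x, path) {
  if (is.matrix(x)) {
    scaled <- if (max(x) <= 1) x else x / 255
  } else if (is.array(x) && length(dim(x)) == 3L) {
    scaled <- x / 255
  } else {
    abort("`x` must be a matrix or an H x W x 3 array.")
  }
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  png::writePNG(scaled, target = path)
  invisible(path)
}
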