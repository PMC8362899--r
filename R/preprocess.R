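#' Green and red color-difference indices
#'
#' Computes a per-pixel color-difference index that enhances either the green
#' (leaf) or the red (tray) component of a plug-tray image while suppressing
#' the others:
#' \deqn{TG = (3G - R - B)/3, \qquad TR = (3R - G - B)/3}
#' The three scene materials — green leaves, brown-black substrate, red tray —
#' are far apart under these indices, which is what makes a simple threshold
#' segmentation work. Values are real (possibly negative); use
#' [quantize_gray()] to rescale to integer levels 0..255 before histogramming.
#'
#' @param image An `H x W x 3` array, channels R, G, B, values in `[0, 255]`.
#' @param index `"tg"` (enhance green) or `"tr"` (enhance red).
#' @return A numeric `H x W` matrix of real index values.
#' @examples
#' px <- array(c(30, 150, 30), dim = c(1, 1, 3))
#' color_index(px, "tg") # 130
#' @seealso [to_grayscale()], [quantize_gray()]
#' @export
color_index <- function(image, index = c("tg", "tr")) {
  index <- match.arg(index)
  assert_rgb_image(image)
  r <- image[, , 1]
  g <- image[, , 2]
  b <- image[, , 3]
  out <- switch(index,
    tg = (3 * g - r - b) / 3,
    tr = (3 * r - g - b) / 3
  )
  matrix(out, nrow = dim(image)[1])
}

#' Luminance grayscale conversion
#'
#' Standard luma conversion `Y = 0.2989 R + 0.5870 G + 0.1141 B`, yielding a
#' gray image in `[0, 255]`.
#'
#' @inheritParams color_index
#' @return A numeric `H x W` matrix in `[0, 255]`.
#' @export
to_grayscale <- function(image) {
  assert_rgb_image(image)
  y <- 0.2989 * image[, , 1] + 0.5870 * image[, , 2] + 0.1141 * image[, , 3]
  matrix(y, nrow = dim(image)[1])
}

#' Quantize a real-valued gray image to integer levels 0..255
#'
#' Color-difference indices can be negative, but entropy thresholding indexes
#' discrete gray levels 0..255. This min-max rescales the image to `[0, 255]`
#' (preserving intensity ordering) and rounds half-up to integers. A constant
#' image maps to level 0. With `rescale = FALSE` the values are only rounded
#' and must already lie in `[0, 255]`.
#'
#' @param gray A numeric matrix of intensities.
#' @param rescale Min-max rescale to `[0, 255]` first? Default `TRUE`.
#' @return An integer-valued matrix with levels in 0..255.
#' @export
quantize_gray <- function(gray, rescale = TRUE) {
  assert_gray_image(gray)
  if (rescale) {
    lo <- min(gray)
    hi <- max(gray)
    gray <- if (hi > lo) (gray - lo) / (hi - lo) * 255 else gray * 0
  }
  out <- round_half_up(gray)
  if (min(out) < 0 || max(out) > 255) {
    abort("Quantized levels fall outside 0..255; use `rescale = TRUE`.")
  }
  out
}

#' Gray-level occurrence histogram
#'
#' Tabulates the probability of occurrence of each of the 256 gray levels of a
#' quantized image — the `P_i` that the maximum-entropy threshold criterion is
#' computed from.
#'
#' @param gray An integer-valued matrix with levels 0..255 (see
#'   [quantize_gray()]).
#' @return A tibble with columns `level` (0..255), `count` and `prob`
#'   (`count / total`), of class `intensity_histogram`, with the pixel total in
#'   `attr(, "total_pixels")`.
#' @examples
#' h <- intensity_histogram(matrix(c(0, 0, 255, 255), 2))
#' h[h$count > 0, ]
#' @export
intensity_histogram <- function(gray) {
  assert_quantized(gray)
  counts <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  total <- length(gray)
  out <- tibble(
    level = 0:255,
    count = counts,
    prob = counts / total
  )
  attr(out, "total_pixels") <- total
  class(out) <- c("intensity_histogram", class(out))
  out
}

# Accept an intensity_histogram tibble or a bare 256-vector of probabilities.
as_prob_vector <- function(hist) {
  if (inherits(hist, "intensity_histogram") ||
    (is.data.frame(hist) && all(c("level", "prob") %in% names(hist)))) {
    p <- numeric(256)
    p[hist$level + 1L] <- hist$prob
  } else if (is.numeric(hist) && length(hist) == 256L) {
    p <- as.numeric(hist)
  } else {
    abort("`hist` must be an intensity_histogram or a numeric vector of 256 probabilities.")
  }
  if (anyNA(p) || any(p < 0)) {
    abort("Histogram probabilities must be non-negative and finite.")
  }
  s <- sum(p)
  if (abs(s - 1) > 1e-6) {
    abort(sprintf("Histogram probabilities must sum to 1 (got %.6f).", s))
  }
  p
}
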