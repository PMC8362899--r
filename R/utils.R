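# Internal helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would
# make quantized gray levels platform-stable but history-dependent on the
# exact float; half-up is the documented convention.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
# `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

assert_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort(sprintf("`%s` must be an H x W x 3 array (channels in R, G, B order).", arg))
  }
  d <- dim(image)
  if (d[1] < 1L || d[2] < 1L) {
    abort(sprintf("`%s` is empty: height and width must be at least 1 pixel.", arg))
  }
  if (anyNA(image) || any(!is.finite(image))) {
    abort(sprintf("`%s` contains missing or non-finite pixel values.", arg))
  }
  if (min(image) < 0 || max(image) > 255) {
    abort(sprintf("`%s` must have 8-bit channel values in [0, 255].", arg))
  }
  invisible(image)
}

assert_gray_image <- function(gray, arg = "gray") {
  if (!is.matrix(gray)) {
    abort(sprintf("`%s` must be a numeric matrix (one intensity per pixel).", arg))
  }
  if (nrow(gray) < 1L || ncol(gray) < 1L) {
    abort(sprintf("`%s` is empty.", arg))
  }
  if (anyNA(gray) || any(!is.finite(gray))) {
    abort(sprintf("`%s` contains missing or non-finite pixel values.", arg))
  }
  invisible(gray)
}

assert_quantized <- function(gray, arg = "gray") {
  assert_gray_image(gray, arg)
  if (min(gray) < 0 || max(gray) > 255 || any(gray != trunc(gray))) {
    abort(sprintf(
      "`%s` must be quantized to integer gray levels 0..255 (see `quantize_gray()`).",
      arg
    ))
  }
  invisible(gray)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
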