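#' Binarize a quantized gray image with a threshold pair
#'
#' Maps gray levels to a 0/1 seedling mask (1 = seedling pixel, 0 =
#' background). Three readings of the two-threshold rule are provided:
#' \describe{
#'   \item{`geq_min`}{pixel is foreground iff its level is `>= min(t1, t2)` —
#'     the literal threshold rule (default here).}
#'   \item{`upper_class`}{foreground iff level `> t2` — the top entropy class
#'     only. This is what the grading pipeline uses: with the green index the
#'     materials order tray < substrate < leaf, so only the top class is leaf.}
#'   \item{`band`}{foreground iff `t1 < level <= t2` — the middle class.}
#' }
#'
#' @param gray Integer-valued matrix with levels 0..255.
#' @param t1,t2 The two thresholds (any order; `min`/`max` taken as needed).
#' @param mode One of `"geq_min"`, `"upper_class"`, `"band"`.
#' @return An integer `H x W` matrix of 0s and 1s.
#' @examples
#' g <- matrix(c(100, 10, 200, 150), 2)
#' binarize(g, 90, 180, "geq_min")
#' binarize(g, 90, 180, "upper_class")
#' @export
binarize <- function(gray, t1, t2, mode = c("geq_min", "upper_class", "band")) {
  mode <- match.arg(mode)
  assert_quantized(gray)
  if (!is_scalar_number(t1) || !is_scalar_number(t2)) {
    abort("`t1` and `t2` must be single gray levels.")
  }
  lo <- min(t1, t2)
  hi <- max(t1, t2)
  out <- switch(mode,
    geq_min = gray >= lo,
    upper_class = gray > hi,
    band = gray > lo & gray <= hi
  )
  mask <- matrix(as.integer(out), nrow = nrow(gray))
  mask
}
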