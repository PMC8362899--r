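#' Two-threshold maximum-entropy criterion
#'
#' Kapur-style objective for a pair of gray-level thresholds `t1 < t2`: the
#' gray levels are split into three classes `[0, t1]`, `(t1, t2]` and
#' `(t2, 255]`, and the criterion is the sum of the three within-class Shannon
#' entropies
#' \deqn{F(t_1,t_2) = -\sum_{k} \sum_{i \in C_k} \frac{P_i}{P_{C_k}}
#'   \ln \frac{P_i}{P_{C_k}}}
#' with class masses \eqn{P_{C_k}} as normalizers. Conventions: a term with
#' `P_i = 0` contributes 0 (the usual `0 ln 0 = 0`), and an empty class
#' (zero mass) contributes 0. Natural logarithm throughout.
#'
#' @param hist An [intensity_histogram()] (or a 256-vector of probabilities).
#' @param t1,t2 Integer gray levels with `0 <= t1 < t2 <= 255`.
#' @return The entropy criterion (a non-negative scalar).
#' @examples
#' h <- intensity_histogram(matrix(0:255, 16)) # uniform
#' entropy_fitness(h, 85, 170) # log(86) + 2 log(85)
#' @export
entropy_fitness <- function(hist, t1, t2) {
  p <- as_prob_vector(hist)
  if (!is_scalar_number(t1) || !is_scalar_number(t2)) {
    abort("`t1` and `t2` must be single gray levels.")
  }
  if (t1 < 0 || t2 > 255 || t1 >= t2) {
    abort("Thresholds must satisfy 0 <= t1 < t2 <= 255.")
  }
  class_entropy <- function(idx) {
    mass <- sum(p[idx])
    if (mass <= 0) {
      return(0)
    }
    q <- p[idx]
    q <- q[q > 0]
    -sum(q / mass * log(q / mass))
  }
  class_entropy(seq_len(t1 + 1L)) +
    class_entropy(seq.int(t1 + 2L, t2 + 1L)) +
    class_entropy(seq.int(t2 + 2L, 256L))
}

#' Exhaustive-search optimal threshold pair
#'
#' Evaluates the maximum-entropy criterion over all 32,640 pairs
#' `0 <= t1 < t2 <= 255` and returns an argmax. Ties are broken by the
#' lexicographically smallest `(t1, t2)`. This serves as the exact reference
#' against which the genetic-algorithm optimizer is validated, and is fast
#' enough (cumulative-sum evaluation) for routine use on its own.
#'
#' @inheritParams entropy_fitness
#' @return A list with `t1`, `t2` and `fitness`.
#' @seealso [ga_thresholds()]
#' @export
brute_force_thresholds <- function(hist) {
  p <- as_prob_vector(hist)
  fit <- entropy_pair_matrix(p)
  best <- max(fit, na.rm = TRUE)
  idx <- which(fit == best, arr.ind = TRUE)
  # rows are t1 + 1, cols are t2; order candidates lexicographically
  ord <- order(idx[, 1], idx[, 2])
  t1 <- unname(idx[ord[1], 1]) - 1L
  t2 <- unname(idx[ord[1], 2])
  list(t1 = as.integer(t1), t2 = as.integer(t2), fitness = best)
}

# Criterion for every pair, as a 255 x 255 matrix indexed [t1 + 1, t2]
# (t1 in 0..254, t2 in 1..255; invalid cells NA). Uses prefix sums of p and
# p log p so the whole sweep is O(levels^2).
entropy_pair_matrix <- function(p) {
  plogp <- ifelse(p > 0, p * log(p), 0)
  cp <- cumsum(p)
  cl <- cumsum(plogp)
  # class [a..b] (1-based): mass = cp[b] - cp[a-1]; sum p log p likewise
  seg_entropy <- function(mass, s) {
    ifelse(mass > 0, log(pmax(mass, .Machine$double.xmin)) - s / pmax(mass, .Machine$double.xmin), 0)
  }
  t1 <- 0:254
  t2 <- 1:255
  m1 <- cp[t1 + 1L]
  s1 <- cl[t1 + 1L]
  h1 <- seg_entropy(m1, s1)
  m3 <- cp[256L] - cp[t2 + 1L]
  s3 <- cl[256L] - cl[t2 + 1L]
  h3 <- seg_entropy(m3, s3)
  # middle class (t1, t2]: mass = cp[t2+1] - cp[t1+1]
  m2 <- outer(cp[t1 + 1L], cp[t2 + 1L], function(a, b) b - a)
  s2 <- outer(cl[t1 + 1L], cl[t2 + 1L], function(a, b) b - a)
  m2[m2 < 0] <- 0 # guard tiny negative rounding
  h2 <- ifelse(m2 > 0, log(pmax(m2, .Machine$double.xmin)) - s2 / pmax(m2, .Machine$double.xmin), 0)
  fit <- outer(h1, h3, `+`) + h2
  fit[outer(t1, t2, `>=`)] <- NA_real_
  fit
}
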