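#' BM3D configuration
#'
#' Tuning parameters for block-matching 3D-transform denoising. Blocks of
#' `block_size` x `block_size` pixels slide on a stride-`step` lattice; for
#' each reference block, similar blocks within `search_radius` pixels whose
#' step-normalized distance is below `distance_threshold` are stacked (at most
#' `max_stack` of them), the stack is filtered in a 3D orthonormal DCT domain
#' by hard thresholding at `lambda_3d * sigma`, and overlapping block
#' estimates are averaged with per-stack weights.
#'
#' Defaults are tuned for cleaning a segmented 0/1 seedling mask treated as a
#' real-valued image (`sigma` is on that 0–1 mask scale).
#'
#' @param block_size Side length K of a square block (>= 2).
#' @param step Stride h of the block lattice; also normalizes the matching
#'   distance `d = ||X_P - X_Q|| / h`.
#' @param search_radius Half-width of the square search window, in pixels.
#' @param distance_threshold Matching threshold `tau_d` on `d`.
#' @param max_stack Maximum number of blocks per stack.
#' @param lambda_3d Hard-threshold multiplier.
#' @param sigma Noise level, in the intensity units of the image being
#'   denoised.
#' @return A `bm3d_config` list.
#' @export
bm3d_config <- function(block_size = 8L, step = 4L, search_radius = 16L,
                        distance_threshold = 1.0, max_stack = 16L,
                        lambda_3d = 2.7, sigma = 0.25) {
  if (!is_scalar_number(block_size) || block_size < 2) {
    abort("`block_size` must be at least 2.")
  }
  if (!is_scalar_number(step) || step < 1) {
    abort("`step` must be at least 1.")
  }
  if (!is_scalar_number(distance_threshold) || distance_threshold <= 0) {
    abort("`distance_threshold` must be positive.")
  }
  if (!is_scalar_number(max_stack) || max_stack < 1) {
    abort("`max_stack` must be at least 1.")
  }
  if (!is_scalar_number(sigma) || sigma < 0) {
    abort("`sigma` must be non-negative.")
  }
  structure(
    list(
      block_size = as.integer(block_size), step = as.integer(step),
      search_radius = as.integer(search_radius),
      distance_threshold = distance_threshold,
      max_stack = as.integer(max_stack),
      lambda_3d = lambda_3d, sigma = sigma
    ),
    class = "bm3d_config"
  )
}

# Orthonormal DCT-II matrix of order n (rows are basis vectors).
dct_matrix <- function(n) {
  if (n == 1L) {
    return(matrix(1, 1, 1))
  }
  k <- 0:(n - 1)
  m <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  m[1, ] <- sqrt(1 / n)
  m
}

# Lattice of top-left block positions along an axis of length len: stride
# `step`, with the final position appended so the last K pixels are covered.
block_lattice <- function(len, k, step) {
  last <- len - k + 1L
  pos <- seq.int(1L, last, by = step)
  if (pos[length(pos)] != last) {
    pos <- c(pos, last)
  }
  as.integer(pos)
}

#' Group similar blocks around a reference block
#'
#' Collects, for the `block_size` x `block_size` block whose top-left pixel is
#' `ref_position`, all candidate blocks on the stride-`step` lattice within
#' the search window whose step-normalized Euclidean distance
#' `d = ||X_P - X_Q|| / step` is below `distance_threshold`. The reference
#' block itself is always the first member (distance 0); the rest are sorted
#' by ascending distance, ties in scan order (left to right, top to bottom),
#' and the stack is truncated to `max_stack` members.
#'
#' @param image A numeric matrix.
#' @param ref_position `c(row, col)` of the reference block's top-left pixel
#'   (1-based); the block must lie fully inside the image.
#' @param config A [bm3d_config()].
#' @return A `block_stack`: list with `ref_position`, `positions` (an
#'   `m x 2` matrix of top-left corners), `distances`, and `blocks`
#'   (`K x K x m` array).
#' @export
match_blocks <- function(image, ref_position, config = bm3d_config()) {
  assert_gray_image(image, "image")
  k <- config$block_size
  h <- config$step
  r0 <- ref_position[1]
  c0 <- ref_position[2]
  if (r0 < 1 || c0 < 1 || r0 + k - 1 > nrow(image) || c0 + k - 1 > ncol(image)) {
    abort("Reference block does not lie fully inside the image.")
  }
  ref_block <- image[r0:(r0 + k - 1), c0:(c0 + k - 1)]

  rpos <- block_lattice(nrow(image), k, h)
  cpos <- block_lattice(ncol(image), k, h)
  rpos <- rpos[abs(rpos - r0) <= config$search_radius]
  cpos <- cpos[abs(cpos - c0) <= config$search_radius]

  cand <- expand.grid(row = rpos, col = cpos)
  cand <- cand[!(cand$row == r0 & cand$col == c0), , drop = FALSE]
  d <- vapply(seq_len(nrow(cand)), function(i) {
    q <- image[cand$row[i]:(cand$row[i] + k - 1), cand$col[i]:(cand$col[i] + k - 1)]
    sqrt(sum((ref_block - q)^2)) / h
  }, numeric(1))
  keep <- d < config$distance_threshold
  cand <- cand[keep, , drop = FALSE]
  d <- d[keep]
  scan_rank <- (cand$row - 1) * ncol(image) + cand$col
  ord <- order(d, scan_rank)
  cand <- cand[ord, , drop = FALSE]
  d <- d[ord]

  positions <- rbind(c(r0, c0), as.matrix(cand))
  distances <- c(0, d)
  m <- min(nrow(positions), config$max_stack)
  positions <- positions[seq_len(m), , drop = FALSE]
  distances <- distances[seq_len(m)]
  blocks <- array(0, dim = c(k, k, m))
  for (i in seq_len(m)) {
    blocks[, , i] <- image[
      positions[i, 1]:(positions[i, 1] + k - 1),
      positions[i, 2]:(positions[i, 2] + k - 1)
    ]
  }
  dimnames(positions) <- list(NULL, c("row", "col"))
  structure(
    list(
      ref_position = c(row = r0, col = c0),
      positions = positions, distances = distances, blocks = blocks
    ),
    class = "block_stack"
  )
}

# Forward 3D transform of a K x K x m block array: orthonormal 2D DCT per
# slice, then orthonormal 1D DCT across the stack. Returns a (K*K) x m
# coefficient matrix; element [1, 1] is the DC term.
dct3_forward <- function(blocks) {
  k <- dim(blocks)[1]
  m <- dim(blocks)[3]
  d2 <- kronecker(dct_matrix(k), dct_matrix(k))
  coef2 <- d2 %*% matrix(blocks, k * k, m)
  coef2 %*% t(dct_matrix(m))
}

dct3_inverse <- function(coefs, k) {
  m <- ncol(coefs)
  d2 <- kronecker(dct_matrix(k), dct_matrix(k))
  back <- coefs %*% dct_matrix(m)
  array(t(d2) %*% back, dim = c(k, k, m))
}

#' Hard-threshold a block stack in the 3D transform domain
#'
#' Applies the forward 3D orthonormal DCT to the stack, zeroes every
#' coefficient whose magnitude is at most `lambda_3d * sigma`, and
#' inverse-transforms. The DC coefficient is exempt from thresholding so that
#' flat regions are preserved exactly. Also reports `n_nonzero`, the number of
#' coefficients surviving the threshold, which drives the aggregation weight
#' ([basic_weight()]).
#'
#' @param stack A `block_stack` from [match_blocks()].
#' @param config A [bm3d_config()].
#' @return A list with `stack` (the filtered `block_stack`) and `n_nonzero`.
#' @export
hard_threshold_filter <- function(stack, config = bm3d_config()) {
  if (!inherits(stack, "block_stack")) {
    abort("`stack` must be a block_stack from `match_blocks()`.")
  }
  k <- dim(stack$blocks)[1]
  coefs <- dct3_forward(stack$blocks)
  thr <- config$lambda_3d * config$sigma
  keep <- abs(coefs) > thr
  keep[1, 1] <- TRUE
  coefs[!keep] <- 0
  n_nonzero <- sum(coefs != 0)
  out <- stack
  out$blocks <- dct3_inverse(coefs, k)
  list(stack = out, n_nonzero = as.integer(n_nonzero))
}

#' Aggregation weight of a hard-thresholded stack
#'
#' The weight given to a stack's block estimates when overlapping estimates
#' are averaged: `1 / N_P` for `N_P >= 1` surviving coefficients, 1 otherwise.
#' Sparser stacks (fewer surviving coefficients) are considered more reliable
#' and weigh more.
#'
#' @param n_nonzero Number of nonzero coefficients after thresholding (>= 0).
#' @return A positive scalar weight.
#' @export
basic_weight <- function(n_nonzero) {
  if (!is_scalar_number(n_nonzero) || n_nonzero < 0) {
    abort("`n_nonzero` must be a non-negative count.")
  }
  if (n_nonzero >= 1) 1 / n_nonzero else 1
}

#' Empirical Wiener aggregation weight
#'
#' Energy-based weight `E / (E + sigma^2)` for the optional second
#' (Wiener-weighted) pass, where `E` is the squared magnitude of the
#' transformed stack. It approaches 1 when the stack energy dominates the
#' noise (a clean stack) and 0 for an all-noise stack; it is strictly
#' increasing in `E` for `sigma > 0`.
#'
#' @param coeff_energy Squared magnitude of the transformed stack (>= 0).
#' @param config A [bm3d_config()] supplying `sigma`.
#' @return A weight in `[0, 1]`.
#' @export
wiener_weight <- function(coeff_energy, config = bm3d_config()) {
  if (!is_scalar_number(coeff_energy) || coeff_energy < 0) {
    abort("`coeff_energy` must be non-negative.")
  }
  if (config$sigma == 0) {
    return(1)
  }
  coeff_energy / (coeff_energy + config$sigma^2)
}

#' Denoise an image by block-matching and 3D transform-domain filtering
#'
#' Full BM3D pass: the image is reflect-padded by `block_size - 1` pixels so
#' every pixel is covered; every block on the stride-`step` lattice serves as
#' a reference; its stack of similar blocks is hard-thresholded in the 3D DCT
#' domain; and each output pixel is the weight-normalized average of all
#' filtered block estimates covering it. The default single pass uses
#' [basic_weight()]; `passes = 2` re-runs the machinery on the first-pass
#' estimate using the energy-based [wiener_weight()].
#'
#' In the seedling pipeline this is applied to the segmented 0/1 mask treated
#' as a real-valued image (then re-binarized at 0.5), which removes isolated
#' noise pixels and fills small holes in leaf regions.
#'
#' @param image A numeric matrix, at least `block_size` pixels in each
#'   dimension.
#' @param config A [bm3d_config()].
#' @param passes 1 (hard-threshold pass, default) or 2 (adds the
#'   Wiener-weighted pass).
#' @return A `bm3d_result`: list with `estimate` (matrix, same size as
#'   `image`), `n_nonzero` (per-stack surviving-coefficient counts) and
#'   `weights` (per-stack aggregation weights).
#' @examples
#' img <- matrix(0, 32, 32)
#' img[8:24, 8:24] <- 1
#' noisy <- img + rnorm(length(img), sd = 0.2)
#' res <- bm3d_denoise(noisy, bm3d_config(sigma = 0.2))
#' mean((res$estimate - img)^2) < mean((noisy - img)^2)
#' @export
bm3d_denoise <- function(image, config = bm3d_config(), passes = 1L) {
  assert_gray_image(image, "image")
  k <- config$block_size
  if (nrow(image) < k || ncol(image) < k) {
    abort("`image` must be at least `block_size` pixels in each dimension.")
  }
  if (!passes %in% c(1L, 2L)) {
    abort("`passes` must be 1 or 2.")
  }
  first <- bm3d_pass(image, config, weight_mode = "basic")
  if (passes == 1L) {
    return(structure(first, class = "bm3d_result"))
  }
  second <- bm3d_pass(first$estimate, config, weight_mode = "wiener")
  structure(second, class = "bm3d_result")
}

# One aggregation pass. All lattice blocks are pre-extracted into a
# (K*K) x N matrix and pre-transformed by the 2D DCT once; per-stack work is
# then a pair of small matrix products, and aggregation is accumulated per
# lattice block in the 2D-DCT domain (the 2D transform is orthonormal, so the
# final inverse can be applied once to the accumulated matrix).
bm3d_pass <- function(image, cfg, weight_mode) {
  k <- cfg$block_size
  h <- cfg$step
  pad <- k - 1L
  y <- reflect_pad(image, pad)
  hp <- nrow(y)
  wp <- ncol(y)

  rpos <- block_lattice(hp, k, h)
  cpos <- block_lattice(wp, k, h)
  nr <- length(rpos)
  nc <- length(cpos)
  n <- nr * nc

  # (K*K) x N matrix of all lattice blocks, column-major over the (nr x nc)
  # grid of positions.
  b <- matrix(0, k * k, n)
  for (dc in 0:(k - 1)) {
    for (dr in 0:(k - 1)) {
      b[dc * k + dr + 1L, ] <- as.vector(y[rpos + dr, cpos + dc, drop = FALSE])
    }
  }
  d2 <- kronecker(dct_matrix(k), dct_matrix(k))
  bd <- d2 %*% b
  dm_list <- lapply(seq_len(cfg$max_stack), dct_matrix)

  # search window index ranges along each lattice axis
  r_lo <- findInterval(rpos - cfg$search_radius - 1L, rpos) + 1L
  r_hi <- findInterval(rpos + cfg$search_radius, rpos)
  c_lo <- findInterval(cpos - cfg$search_radius - 1L, cpos) + 1L
  c_hi <- findInterval(cpos + cfg$search_radius, cpos)

  thr <- cfg$lambda_3d * cfg$sigma
  acc <- matrix(0, k * k, n) # weighted filtered blocks, 2D-DCT domain
  wsum <- numeric(n)
  n_nonzero <- integer(n)
  weights <- numeric(n)

  idx <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      idx <- idx + 1L
      ref <- (j - 1L) * nr + i
      ii <- r_lo[i]:r_hi[i]
      jj <- c_lo[j]:c_hi[j]
      cand <- as.vector(outer(ii, (jj - 1L) * nr, `+`))
      diffs <- b[, cand, drop = FALSE] - b[, ref]
      d <- sqrt(colSums(diffs * diffs)) / h
      sel <- which(d < cfg$distance_threshold & cand != ref)
      # scan order: left to right then top to bottom
      cand_i <- ((cand[sel] - 1L) %% nr) + 1L
      cand_j <- ((cand[sel] - 1L) %/% nr) + 1L
      ord <- order(d[sel], (cand_i - 1L) * nc + cand_j)
      mem <- c(ref, cand[sel][ord])
      m <- min(length(mem), cfg$max_stack)
      mem <- mem[seq_len(m)]

      dm <- dm_list[[m]]
      coefs <- bd[, mem, drop = FALSE] %*% t(dm)
      keep <- abs(coefs) > thr
      keep[1, 1] <- TRUE
      coefs[!keep] <- 0
      np <- sum(coefs != 0)
      w <- if (weight_mode == "basic") {
        if (np >= 1) 1 / np else 1
      } else {
        e <- sum(coefs * coefs)
        if (cfg$sigma == 0) 1 else e / (e + cfg$sigma^2)
      }
      filtered <- coefs %*% dm
      acc[, mem] <- acc[, mem] + w * filtered
      wsum[mem] <- wsum[mem] + w
      n_nonzero[idx] <- np
      weights[idx] <- w
    }
  }

  spatial <- t(d2) %*% acc
  num <- matrix(0, hp, wp)
  den <- matrix(0, hp, wp)
  idx <- 0L
  for (j in seq_len(nc)) {
    cc <- cpos[j]:(cpos[j] + k - 1L)
    for (i in seq_len(nr)) {
      idx <- idx + 1L
      rr <- rpos[i]:(rpos[i] + k - 1L)
      num[rr, cc] <- num[rr, cc] + matrix(spatial[, (j - 1L) * nr + i], k, k)
      den[rr, cc] <- den[rr, cc] + wsum[(j - 1L) * nr + i]
    }
  }
  est <- num / den
  est <- est[(pad + 1L):(pad + nrow(image)), (pad + 1L):(pad + ncol(image))]
  list(estimate = est, n_nonzero = n_nonzero, weights = weights)
}

# Half-sample symmetric padding on all four sides.
reflect_pad <- function(x, pad) {
  if (pad == 0L) {
    return(x)
  }
  ri <- c(pad:1, seq_len(nrow(x)), nrow(x):(nrow(x) - pad + 1L))
  ci <- c(pad:1, seq_len(ncol(x)), ncol(x):(ncol(x) - pad + 1L))
  x[ri, ci, drop = FALSE]
}
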