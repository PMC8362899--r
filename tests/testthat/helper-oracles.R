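# Independent, deliberately naive reference implementations used as oracles.
# These recompute quantities term by term, straight from the defining
# formulas, sharing no code with the package internals.

# Three-class entropy criterion, summed term by term.
slow_entropy <- function(p, t1, t2) {
  classes <- list(0:t1, (t1 + 1):t2, if (t2 < 255) (t2 + 1):255 else integer(0))
  total <- 0
  for (cls in classes) {
    mass <- sum(p[cls + 1])
    if (mass == 0) next
    for (i in cls) {
      pi <- p[i + 1]
      if (pi > 0) {
        total <- total - (pi / mass) * log(pi / mass)
      }
    }
  }
  total
}

# Double loop over every threshold pair; vector arithmetic per pair but no
# prefix sums. Ties resolved to the smallest (t1, t2).
slow_brute_force <- function(p) {
  logp <- ifelse(p > 0, log(p), 0)
  pair_fit <- function(t1, t2) {
    h <- 0
    for (cls in list(0:t1, (t1 + 1):t2, if (t2 < 255) (t2 + 1):255 else integer(0))) {
      q <- p[cls + 1]
      mass <- sum(q)
      if (mass > 0) {
        h <- h + log(mass) - sum(q * logp[cls + 1]) / mass
      }
    }
    h
  }
  best <- -Inf
  best_pair <- c(NA, NA)
  for (t1 in 0:254) {
    for (t2 in (t1 + 1):255) {
      f <- pair_fit(t1, t2)
      if (f > best) {
        best <- f
        best_pair <- c(t1, t2)
      }
    }
  }
  list(t1 = best_pair[1], t2 = best_pair[2], fitness = best)
}

# Exhaustive block matcher: scans every lattice candidate in the window.
slow_match_blocks <- function(image, ref, cfg) {
  k <- cfg$block_size
  h <- cfg$step
  get_block <- function(r, c) image[r:(r + k - 1), c:(c + k - 1)]
  ref_block <- get_block(ref[1], ref[2])
  lattice <- function(len) {
    pos <- seq(1, len - k + 1, by = h)
    if (pos[length(pos)] != len - k + 1) pos <- c(pos, len - k + 1)
    pos
  }
  rows <- c()
  cols <- c()
  ds <- c()
  for (r in lattice(nrow(image))) {
    for (c in lattice(ncol(image))) {
      if (abs(r - ref[1]) > cfg$search_radius || abs(c - ref[2]) > cfg$search_radius) next
      if (r == ref[1] && c == ref[2]) next
      d <- sqrt(sum((ref_block - get_block(r, c))^2)) / h
      if (d < cfg$distance_threshold) {
        rows <- c(rows, r)
        cols <- c(cols, c)
        ds <- c(ds, d)
      }
    }
  }
  ord <- order(ds, (rows - 1) * ncol(image) + cols)
  pos <- rbind(ref, cbind(rows, cols)[ord, , drop = FALSE])
  d_all <- c(0, ds[ord])
  m <- min(nrow(pos), cfg$max_stack)
  list(positions = unname(pos[seq_len(m), , drop = FALSE]), distances = d_all[seq_len(m)])
}

# Straight-line DCT transform -> hard threshold -> inverse on a block array,
# built from the cosine definition (not the package's matrix code).
slow_filter_stack <- function(blocks, lambda, sigma) {
  dct1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (k in 0:(n - 1)) {
      s <- 0
      for (j in 0:(n - 1)) s <- s + v[j + 1] * cos(pi * (2 * j + 1) * k / (2 * n))
      out[k + 1] <- s * if (k == 0) sqrt(1 / n) else sqrt(2 / n)
    }
    out
  }
  idct1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (j in 0:(n - 1)) {
      s <- v[1] * sqrt(1 / n)
      if (n > 1) {
        for (k in 1:(n - 1)) {
          s <- s + v[k + 1] * sqrt(2 / n) * cos(pi * (2 * j + 1) * k / (2 * n))
        }
      }
      out[j + 1] <- s
    }
    out
  }
  k <- dim(blocks)[1]
  m <- dim(blocks)[3]
  co <- blocks
  for (i in seq_len(m)) co[, , i] <- apply(co[, , i], 2, dct1)
  for (i in seq_len(m)) co[, , i] <- t(apply(co[, , i], 1, dct1))
  for (r in seq_len(k)) {
    for (c in seq_len(k)) co[r, c, ] <- dct1(co[r, c, ])
  }
  thr <- lambda * sigma
  keep <- abs(co) > thr
  keep[1, 1, 1] <- TRUE
  co[!keep] <- 0
  n_nonzero <- sum(co != 0)
  for (r in seq_len(k)) {
    for (c in seq_len(k)) co[r, c, ] <- idct1(co[r, c, ])
  }
  for (i in seq_len(m)) co[, , i] <- t(apply(co[, , i], 1, idct1))
  for (i in seq_len(m)) co[, , i] <- apply(co[, , i], 2, idct1)
  list(blocks = co, n_nonzero = n_nonzero)
}

# A smooth multi-modal gray-level histogram (mixture of Gaussians over a
# uniform floor), as produced by well-separated scene materials.
random_smooth_histogram <- function(n_modes = 3) {
  x <- 0:255
  dens <- rep(0.05 / 256, 256)
  weights <- runif(n_modes, 0.5, 1.5)
  weights <- weights / sum(weights) * 0.95
  for (i in seq_len(n_modes)) {
    mu <- runif(1, 20, 235)
    sd <- runif(1, 8, 30)
    d <- dnorm(x, mu, sd)
    dens <- dens + weights[i] * d / sum(d)
  }
  dens / sum(dens)
}

rgb_pixel <- function(r, g, b) {
  array(c(r, g, b), dim = c(1, 1, 3))
}

random_rgb_image <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}
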