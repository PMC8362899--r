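test_that("block matching groups candidates by normalized distance", {
  cfg <- bm3d_config(block_size = 4, step = 2, search_radius = 6, max_stack = 8)

  # constant image: every candidate at distance 0, scan order, ref first
  st <- match_blocks(matrix(1, 20, 20), c(5, 5), cfg)
  expect_equal(dim(st$blocks)[3], 8)
  expect_equal(unname(st$positions[1, ]), c(5, 5))
  expect_true(all(st$distances == 0))

  # lone structure: small threshold leaves only the reference in the stack
  img <- matrix(0, 20, 20)
  img[5:8, 5:8] <- 10
  st2 <- match_blocks(img, c(5, 5), bm3d_config(
    block_size = 4, step = 2,
    search_radius = 6, distance_threshold = 0.5
  ))
  expect_equal(dim(st2$blocks)[3], 1)
  expect_equal(st2$distances, 0)

  expect_error(match_blocks(matrix(0, 8, 8), c(7, 7), cfg), "inside the image")
})

test_that("block matching agrees with an exhaustive double-loop matcher", {
  set.seed(301)
  cfg <- bm3d_config(
    block_size = 4, step = 2, search_radius = 8,
    distance_threshold = 3, max_stack = 10
  )
  for (i in 1:3) {
    img <- matrix(runif(16 * 16, 0, 2), 16)
    for (ref in list(c(1, 1), c(5, 7), c(13, 13))) {
      got <- match_blocks(img, ref, cfg)
      want <- slow_match_blocks(img, ref, cfg)
      expect_equal(unname(got$positions), unname(want$positions))
      expect_equal(got$distances, want$distances)
    }
  }
})

test_that("hard thresholding is a faithful 3D transform round trip", {
  set.seed(302)
  img <- matrix(runif(16 * 16), 16)
  cfg0 <- bm3d_config(block_size = 4, step = 2, sigma = 0)
  st <- match_blocks(img, c(5, 5), cfg0)
  out <- hard_threshold_filter(st, cfg0)
  # sigma = 0: pure round trip
  expect_equal(out$stack$blocks, st$blocks, tolerance = 1e-8)
  expect_equal(out$n_nonzero, slow_filter_stack(st$blocks, 0, 0)$n_nonzero)

  # constant stack under a huge threshold: only the DC survives, value kept
  cst <- match_blocks(matrix(3, 12, 12), c(3, 3), bm3d_config(block_size = 4, step = 2, sigma = 100))
  outc <- hard_threshold_filter(cst, bm3d_config(block_size = 4, step = 2, sigma = 100))
  expect_equal(outc$stack$blocks, cst$blocks, tolerance = 1e-10)
  expect_equal(outc$n_nonzero, 1L)
})

test_that("hard thresholding matches a straight-line transform oracle", {
  set.seed(303)
  cfg <- bm3d_config(block_size = 4, step = 2, sigma = 0.3, lambda_3d = 2)
  blocks <- array(rnorm(4 * 4 * 4), dim = c(4, 4, 4))
  st <- structure(
    list(
      ref_position = c(1, 1), positions = matrix(1, 4, 2),
      distances = rep(0, 4), blocks = blocks
    ),
    class = "block_stack"
  )
  got <- hard_threshold_filter(st, cfg)
  want <- slow_filter_stack(blocks, cfg$lambda_3d, cfg$sigma)
  expect_equal(got$stack$blocks, want$blocks, tolerance = 1e-10)
  expect_equal(got$n_nonzero, want$n_nonzero)
})

test_that("aggregation weights follow the sparsity and energy rules", {
  expect_equal(basic_weight(4), 0.25)
  expect_equal(basic_weight(0), 1)
  expect_equal(basic_weight(1), 1)
  expect_error(basic_weight(-1), "non-negative")

  cfg <- bm3d_config(sigma = 0.5)
  expect_equal(wiener_weight(0.25, cfg), 0.5) # E = sigma^2
  expect_equal(wiener_weight(0, cfg), 0)
  expect_equal(wiener_weight(3, bm3d_config(sigma = 0)), 1)
  # strictly increasing in energy for sigma > 0
  e <- seq(0, 2, by = 0.1)
  w <- vapply(e, wiener_weight, numeric(1), config = cfg)
  expect_true(all(diff(w) > 0))
})

test_that("denoising is the identity at sigma 0 and preserves flat fields", {
  set.seed(304)
  img <- matrix(runif(40 * 40), 40)
  r0 <- bm3d_denoise(img, bm3d_config(sigma = 0))
  expect_lt(max(abs(r0$estimate - img)), 1e-6)

  for (c in c(0, 0.05, 1, 200)) {
    rc <- bm3d_denoise(matrix(c, 24, 24), bm3d_config(sigma = 0.25))
    expect_equal(rc$estimate, matrix(c, 24, 24))
  }
  expect_error(bm3d_denoise(matrix(0, 4, 4), bm3d_config(block_size = 8)), "at least")
})

test_that("denoising reduces mask error on noisy synthetic leaf masks", {
  for (s in 1:3) {
    set.seed(400 + s)
    clean <- matrix(0, 96, 96)
    clean[20:70, 15:60] <- 1
    clean[40:55, 65:85] <- 1
    noisy <- clean + rnorm(length(clean), sd = 0.25)
    den <- bm3d_denoise(noisy, bm3d_config(sigma = 0.25))
    expect_lt(mean((den$estimate - clean)^2), mean((noisy - clean)^2))
  }
})

test_that("the two-pass variant also reduces error and stays flat-field safe", {
  set.seed(305)
  clean <- matrix(0, 64, 64)
  clean[16:48, 16:48] <- 1
  noisy <- clean + rnorm(length(clean), sd = 0.25)
  den2 <- bm3d_denoise(noisy, bm3d_config(sigma = 0.25), passes = 2)
  expect_lt(mean((den2$estimate - clean)^2), mean((noisy - clean)^2))
  flat <- bm3d_denoise(matrix(2, 24, 24), bm3d_config(sigma = 0.25), passes = 2)
  expect_equal(flat$estimate, matrix(2, 24, 24))
})
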