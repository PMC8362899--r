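test_that("an empty tray renders with zero leaf pixels and empty labels", {
  tray <- generate_tray(synth_spec(per_cell_f = 0, seed = 1))
  expect_equal(sum(tray$mask), 0)
  expect_true(all(tray$truth$label == "empty"))
  expect_equal(dim(tray$image), c(144, 336, 3))
})

test_that("rendered leaf coverage hits the requested fraction", {
  f <- rep(0, 21)
  f[5] <- 0.30
  tray <- generate_tray(synth_spec(per_cell_f = f, seed = 2))
  got <- tray$truth$f[tray$truth$row == 1 & tray$truth$col == 5]
  expect_gte(got, 0.29)
  expect_lte(got, 0.31)

  # several fractions at once
  tray2 <- generate_tray(synth_spec(per_cell_f = seq(0.05, 0.85, length.out = 21), seed = 3))
  expect_true(all(abs(tray2$truth$f - seq(0.05, 0.85, length.out = 21)) <= 0.01))
})

test_that("ground truth equals a recount of the clean mask", {
  tray <- generate_tray(synth_spec(per_cell_f = 0.25, seed = 4))
  recount <- partition_cells(tray$mask, tray_layout())
  expect_equal(tray$truth$pixel_count, recount$pixel_count)
  expect_equal(tray$truth$f, recount$pixel_count / recount$cell_px)
})

test_that("rendering is deterministic per seed", {
  a <- generate_tray(synth_spec(per_cell_f = 0.2, seed = 9))
  b <- generate_tray(synth_spec(per_cell_f = 0.2, seed = 9))
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- generate_tray(synth_spec(per_cell_f = 0.2, seed = 10))
  expect_false(identical(a$image, c$image))
})

test_that("leaf pixels are the brightest material under the green index", {
  spec <- synth_spec(
    per_cell_f = 0.3, seed = 5,
    color_jitter = 0, noise_sigma = 0, illumination_gradient = 0
  )
  tray <- generate_tray(spec)
  tg <- color_index(tray$image, "tg")
  leaf_min <- min(tg[tray$mask == 1])
  bg_max <- max(tg[tray$mask == 0])
  expect_gte(leaf_min - bg_max, 40)
})

test_that("coverage targets outside the renderable range are rejected", {
  expect_error(synth_spec(per_cell_f = 0.95), "\\[0, 0.9\\]")
  expect_error(synth_spec(per_cell_f = rep(0.1, 5)), "entries")
})

test_that("validation groups honor the requested label mix", {
  g <- generate_validation_group(4,
    label_mix = c(healthy = 75, sub_healthy = 6, poor = 2, empty = 1) / 84,
    seed = 42
  )
  counts <- table(g$truth$requested_label)
  expect_equal(sum(counts), 84)
  expect_true(abs(counts[["healthy"]] - 75) <= 1)
  expect_true(abs(counts[["sub_healthy"]] - 6) <= 1)
  # labels derived from rendered coverage agree with the requested ones
  expect_true(all(as.character(g$truth$label) == g$truth$requested_label))

  g2 <- generate_validation_group(4,
    label_mix = c(healthy = 75, sub_healthy = 6, poor = 2, empty = 1) / 84,
    seed = 42
  )
  expect_identical(g$truth, g2$truth)

  all_healthy <- generate_validation_group(1,
    label_mix = c(healthy = 1, sub_healthy = 0, poor = 0, empty = 0),
    seed = 7
  )
  expect_true(all(all_healthy$truth$label == "healthy"))

  expect_error(
    generate_validation_group(1, label_mix = c(healthy = 0.5, sub_healthy = 0.1, poor = 0.1, empty = 0.1)),
    "sum to 1"
  )
  expect_error(generate_validation_group(0), "at least 1")
})
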