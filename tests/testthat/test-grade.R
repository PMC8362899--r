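small_layout <- function() {
  tray_layout(
    n_rows = 2, n_cols = 3,
    region = c(row = 1, col = 1, height = 20, width = 30),
    actual_tray_area = 600
  )
}

test_that("per-cell counting conserves and localizes foreground pixels", {
  layout <- small_layout()
  zero <- partition_cells(matrix(0L, 20, 30), layout)
  expect_equal(zero$pixel_count, rep(0L, 6))

  # one blob fully inside cell (2, 3): rows 11..20, cols 21..30
  m <- matrix(0L, 20, 30)
  m[13:17, 23:26] <- 1L
  p <- partition_cells(m, layout)
  expect_equal(p$pixel_count[p$row == 2 & p$col == 3], 20L)
  expect_equal(sum(p$pixel_count), 20L)

  # blob straddling cells (1,1)/(1,2): split at col 10|11
  m2 <- matrix(0L, 20, 30)
  m2[1:10, 5:14] <- 1L # 10 rows x cols 5..14; col boundary at 10
  p2 <- partition_cells(m2, layout)
  expect_equal(p2$pixel_count[p2$row == 1 & p2$col == 1], 60L)
  expect_equal(p2$pixel_count[p2$row == 1 & p2$col == 2], 40L)

  # conservation against a direct recount, random masks
  set.seed(501)
  for (i in 1:3) {
    mr <- matrix(rbinom(600, 1, 0.3), 20, 30)
    expect_equal(sum(partition_cells(mr, layout)$pixel_count), sum(mr))
  }

  expect_error(partition_cells(matrix(0L, 5, 5), layout), "outside")
})

test_that("uneven tray extents give the remainder to the last row/column", {
  layout <- tray_layout(
    n_rows = 2, n_cols = 3,
    region = c(1, 1, 21, 32), actual_tray_area = 672
  )
  r <- cell_rects(layout)
  expect_equal(sum(r$cell_px), 21 * 32)
  expect_equal(unique(r$r1[r$row == 2]), 21L)
  expect_equal(unique(r$c1[r$col == 3]), 32L)
  # last column absorbs 32 - 3*10 = 2 extra pixels
  row1 <- dplyr::arrange(dplyr::filter(r, row == 1), col)
  expect_equal(row1$c1 - row1$c0 + 1L, c(10L, 10L, 12L))
})

test_that("leaf area scales pixel counts by the tray calibration factor", {
  lay <- tray_layout(n_rows = 1, n_cols = 1, region = c(1, 1, 10, 100), actual_tray_area = 500)
  expect_equal(lay$scale_k, 0.5)
  expect_equal(leaf_area(1000, lay), 500)
  expect_equal(leaf_area(0, lay), 0)
  lay2 <- tray_layout(n_rows = 1, n_cols = 1, region = c(1, 1, 32, 100), actual_tray_area = 1000)
  expect_equal(leaf_area(320, lay2), 100)
  expect_error(leaf_area(-1, lay), "non-negative")
})

test_that("the leaf-cover ratio is a plain pixel fraction", {
  expect_equal(area_ratio(200, 1000), 0.2)
  expect_equal(area_ratio(0, 1000), 0)
  expect_equal(area_ratio(150, 937), 150 / 937)
  expect_error(area_ratio(10, 0), "positive")
})

test_that("grading follows the four-class rule with documented tie-breaks", {
  th <- class_thresholds()
  expect_equal(as.character(classify_seedling(0.22, th)), "healthy")
  expect_equal(as.character(classify_seedling(0.18, th)), "sub_healthy")
  expect_equal(as.character(classify_seedling(0.10, th)), "poor")
  expect_equal(as.character(classify_seedling(0.01, th)), "empty")
  # boundary ties: > is strict at f_avg, inclusive at f_min, strict at f_empty
  expect_equal(as.character(classify_seedling(c(0.20, 0.16, 0.015), th)), c("sub_healthy", "sub_healthy", "poor"))
  expect_error(class_thresholds(f_avg = 0.1, f_min = 0.2), "f_empty < f_min < f_avg")
})

test_that("grading is a monotone step function of the cover ratio", {
  f <- sort(runif(200, 0, 0.4))
  lab <- classify_seedling(f)
  expect_true(all(diff(as.integer(lab)) >= 0))
})

test_that("cell coordinates reproduce the odd-lattice convention and are injective", {
  expect_equal(cell_coordinate(1, 1), tibble::tibble(x = 1L, y = 1L))
  expect_equal(cell_coordinate(3, 6), tibble::tibble(x = 11L, y = 5L))
  expect_equal(cell_coordinate(2, 7), tibble::tibble(x = 13L, y = 3L))
  grid <- expand.grid(row = 1:3, col = 1:7)
  coords <- cell_coordinate(grid$row, grid$col)
  expect_equal(nrow(dplyr::distinct(coords)), 21)
  expect_error(cell_coordinate(4, 1), "out of range")
})

test_that("threshold calibration pools group summaries", {
  tab <- pepper_threshold_groups()
  expect_equal(nrow(tab), 20)
  cal <- calibrate_thresholds(tab)
  expect_equal(cal$pooled$f_avg, 0.20)
  expect_equal(cal$pooled$f_max, 0.25)
  expect_equal(cal$pooled$f_min, 0.15) # group 18's recorded minimum

  # raw-measurement interface
  raw <- tibble::tibble(
    group = rep(1:2, each = 3),
    f = c(0.2, 0.2, 0.2, 0.1, 0.2, 0.3)
  )
  cal2 <- calibrate_thresholds(raw)
  expect_equal(cal2$per_group$f_max, c(0.2, 0.3))
  expect_equal(cal2$per_group$f_avg, c(0.2, 0.2))
  expect_equal(cal2$per_group$f_min, c(0.2, 0.1))
  expect_equal(cal2$pooled$f_avg, 0.2)

  expect_error(calibrate_thresholds(tibble::tibble(group = 1, f_max = 1)), "columns")
})

test_that("identification accuracy reproduces the validation tables", {
  counts <- pepper_group_counts()
  actual <- dplyr::filter(counts, method == "actual")[c("group", "healthy")]
  names(actual)[2] <- "actual_healthy"
  ident <- dplyr::filter(counts, method != "actual")
  data <- dplyr::left_join(
    dplyr::rename(ident[c("group", "method", "healthy")], identified_healthy = healthy),
    actual,
    by = "group"
  )
  res <- evaluate_accuracy(data)
  prop <- dplyr::filter(res$per_group, method == "proposed")
  comp <- dplyr::filter(res$per_group, method == "comparison")
  expect_equal(prop$accuracy, c(96, 92.55, 94.44))
  expect_equal(comp$accuracy, c(92, 87.23, 88.89))
  expect_equal(res$average$average_accuracy[res$average$method == "proposed"], 94.33)
  expect_equal(res$average$average_accuracy[res$average$method == "comparison"], 89.37)

  zero <- evaluate_accuracy(tibble::tibble(
    group = "Z", actual_healthy = 10, identified_healthy = 0
  ))
  expect_equal(zero$per_group$accuracy, 0)
  expect_error(
    evaluate_accuracy(tibble::tibble(group = "Z", actual_healthy = 0, identified_healthy = 0)),
    "undefined"
  )
})
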