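#' Specification for a synthetic plug-tray image
#'
#' Describes a rendered tray scene: a red tray grid, a dark substrate disc in
#' each cell, and green leaf blobs (a union of random ellipses, radially
#' scaled until the in-cell leaf cover matches the requested fraction to
#' within about one pixel). Per-pixel color jitter, a corner-to-corner
#' multiplicative illumination ramp, and additive Gaussian noise emulate
#' camera imperfections. The default palette keeps the green index of leaf
#' pixels at least 40 units above both backgrounds, so threshold segmentation
#' of the rendered scene is well-posed.
#'
#' @param layout A [tray_layout()]; the image spans its tray region.
#' @param per_cell_f Target leaf-cover fraction per cell: a single number, or
#'   a vector/matrix with one entry per cell (row-major). All entries in
#'   `[0, 0.9]`.
#' @param leaf_color,substrate_color,tray_color RGB means in `[0, 255]`.
#' @param color_jitter Per-pixel, per-channel Gaussian sd around the material
#'   color.
#' @param noise_sigma Additive Gaussian noise sd (8-bit intensity units).
#' @param illumination_gradient Relative amplitude `g` of a corner-to-corner
#'   multiplicative ramp spanning `[1 - g, 1 + g]`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(layout = tray_layout(), per_cell_f = 0,
                       leaf_color = c(40, 160, 50),
                       substrate_color = c(60, 45, 35),
                       tray_color = c(200, 30, 30),
                       color_jitter = 8, noise_sigma = 5,
                       illumination_gradient = 0.1, seed = NULL) {
  n_cells <- layout$n_rows * layout$n_cols
  if (length(per_cell_f) == 1L) {
    per_cell_f <- rep(per_cell_f, n_cells)
  }
  if (length(per_cell_f) != n_cells) {
    abort(sprintf("`per_cell_f` must have 1 or %d entries.", n_cells))
  }
  if (any(per_cell_f < 0) || any(per_cell_f > 0.9)) {
    abort("Leaf-cover targets must lie in [0, 0.9].")
  }
  for (col in list(leaf_color, substrate_color, tray_color)) {
    if (length(col) != 3L || any(col < 0) || any(col > 255)) {
      abort("Material colors must be RGB triples in [0, 255].")
    }
  }
  structure(
    list(
      layout = layout,
      per_cell_f = as.numeric(per_cell_f),
      leaf_color = leaf_color, substrate_color = substrate_color,
      tray_color = tray_color, color_jitter = color_jitter,
      noise_sigma = noise_sigma,
      illumination_gradient = illumination_gradient,
      seed = seed
    ),
    class = "synth_spec"
  )
}

#' Render a synthetic tray image with ground truth
#'
#' Renders the scene described by a [synth_spec()] and records, before any
#' noise or illumination is applied, the true per-cell leaf pixel count,
#' leaf-cover ratio and grade label. Deterministic for a fixed seed.
#'
#' @param spec A [synth_spec()].
#' @param thresholds A [class_thresholds()] used to derive the true labels.
#' @return A list with `image` (`H x W x 3` array, `[0, 255]`), `truth`
#'   (tibble: `row`, `col`, `pixel_count`, `cell_px`, `f`, `label`) and
#'   `mask` (the clean 0/1 leaf mask).
#' @examples
#' tray <- generate_tray(synth_spec(per_cell_f = 0.3, seed = 7))
#' dplyr::count(tray$truth, label)
#' @export
generate_tray <- function(spec, thresholds = class_thresholds()) {
  if (!inherits(spec, "synth_spec")) {
    abort("`spec` must be created with `synth_spec()`.")
  }
  layout <- spec$layout
  reg <- layout$region
  h <- reg[["row"]] + reg[["height"]] - 1L
  w <- reg[["col"]] + reg[["width"]] - 1L
  rects <- cell_rects(layout)
  f_target <- matrix(spec$per_cell_f,
    nrow = layout$n_rows, ncol = layout$n_cols, byrow = TRUE
  )

  with_seed(spec$seed, {
    material <- matrix("tray", h, w)
    leaf_mask <- matrix(0L, h, w)

    for (i in seq_len(nrow(rects))) {
      r0 <- rects$r0[i]
      r1 <- rects$r1[i]
      c0 <- rects$c0[i]
      c1 <- rects$c1[i]
      ch <- r1 - r0 + 1L
      cw <- c1 - c0 + 1L
      rr <- outer(seq_len(ch), rep(1, cw))
      cc <- outer(rep(1, ch), seq_len(cw))
      cy <- (ch + 1) / 2
      cx <- (cw + 1) / 2
      disc <- (rr - cy)^2 + (cc - cx)^2 <= (0.45 * min(ch, cw))^2
      cell_mat <- matrix("tray", ch, cw)
      cell_mat[disc] <- "substrate"

      f_cell <- f_target[rects$row[i], rects$col[i]]
      if (f_cell > 0) {
        blob <- render_blob(ch, cw, f_cell)
        cell_mat[blob] <- "leaf"
        leaf_mask[r0:r1, c0:c1][blob] <- 1L
      }
      material[r0:r1, c0:c1] <- cell_mat
    }

    truth <- partition_cells(leaf_mask, layout)
    truth <- dplyr::mutate(truth,
      f = .data$pixel_count / .data$cell_px,
      label = classify_seedling(.data$f, thresholds)
    )

    palette <- rbind(
      tray = spec$tray_color,
      substrate = spec$substrate_color,
      leaf = spec$leaf_color
    )
    img <- array(0, dim = c(h, w, 3L))
    for (ch_i in 1:3) {
      base <- matrix(palette[material, ch_i], h, w)
      base <- base + stats::rnorm(h * w, sd = spec$color_jitter)
      img[, , ch_i] <- base
    }
    g <- spec$illumination_gradient
    if (g != 0) {
      ramp <- 1 + g * (2 * (outer(0:(h - 1), 0:(w - 1), `+`)) / (h + w - 2) - 1)
      for (ch_i in 1:3) img[, , ch_i] <- img[, , ch_i] * ramp
    }
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), sd = spec$noise_sigma)
    }
    img <- round_half_up(img)
    img[img < 0] <- 0
    img[img > 255] <- 255

    list(image = img, truth = truth, mask = leaf_mask)
  })
}

# Union of random ellipses centered near the cell center, radially scaled by
# binary search until the covered pixel count hits the target (within ~2 px).
render_blob <- function(ch, cw, f_cell, n_ellipses = 4L) {
  target <- round(f_cell * ch * cw)
  if (target == 0) {
    return(matrix(FALSE, ch, cw))
  }
  cy <- (ch + 1) / 2
  cx <- (cw + 1) / 2
  half <- min(ch, cw) / 2
  ell <- lapply(seq_len(n_ellipses), function(e) {
    list(
      cy = cy + stats::runif(1, -0.15, 0.15) * ch,
      cx = cx + stats::runif(1, -0.15, 0.15) * cw,
      a = stats::runif(1, 0.20, 0.45) * half,
      b = stats::runif(1, 0.20, 0.45) * half,
      theta = stats::runif(1, 0, pi)
    )
  })
  rr <- outer(seq_len(ch), rep(1, cw))
  cc <- outer(rep(1, ch), seq_len(cw))
  coverage <- function(s) {
    inside <- matrix(FALSE, ch, cw)
    for (e in ell) {
      dy <- rr - e$cy
      dx <- cc - e$cx
      u <- dx * cos(e$theta) + dy * sin(e$theta)
      v <- -dx * sin(e$theta) + dy * cos(e$theta)
      inside <- inside | (u / (s * e$a))^2 + (v / (s * e$b))^2 <= 1
    }
    inside
  }
  lo <- 0
  hi <- 4
  best <- coverage(hi)
  if (sum(best) < target) {
    return(best) # saturated; caller's 0.9 cap makes this unreachable
  }
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    m <- coverage(mid)
    n <- sum(m)
    if (abs(n - target) <= 2) {
      return(m)
    }
    if (n < target) lo <- mid else hi <- mid
  }
  coverage(hi)
}

#' Generate a labeled validation set of synthetic trays
#'
#' Draws a set of trays whose cells carry known grade labels in requested
#' proportions. Cell counts per label follow largest-remainder rounding of
#' the proportions over all cells; true leaf-cover targets are drawn
#' uniformly from disjoint per-label ranges, so every cell's label is
#' unambiguous.
#'
#' @param n_trays Number of trays (>= 1).
#' @param label_mix Named proportions over
#'   `c("healthy", "sub_healthy", "poor", "empty")`; must sum to 1.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param layout A [tray_layout()].
#' @param ranges Named list of `c(lo, hi)` leaf-cover ranges per label.
#' @param ... Passed to [synth_spec()] (noise, palette, ...).
#' @return A list with `trays` (list of [generate_tray()] results) and
#'   `truth` (combined tibble with a `tray` column).
#' @export
generate_validation_group <- function(n_trays,
                                      label_mix = c(
                                        healthy = 75, sub_healthy = 6,
                                        poor = 2, empty = 1
                                      ) / 84,
                                      seed = NULL,
                                      layout = tray_layout(),
                                      ranges = list(
                                        healthy = c(0.22, 0.35),
                                        sub_healthy = c(0.165, 0.195),
                                        poor = c(0.02, 0.15),
                                        empty = c(0, 0.014)
                                      ),
                                      ...) {
  if (!is_scalar_number(n_trays) || n_trays < 1) {
    abort("`n_trays` must be at least 1.")
  }
  if (!setequal(names(label_mix), seedling_labels)) {
    abort("`label_mix` must be named over healthy/sub_healthy/poor/empty.")
  }
  if (abs(sum(label_mix) - 1) > 1e-8) {
    abort("`label_mix` proportions must sum to 1.")
  }
  n_cells <- layout$n_rows * layout$n_cols
  total <- n_trays * n_cells
  counts <- largest_remainder(label_mix[seedling_labels], total)

  with_seed(seed, {
    labels <- sample(rep(seedling_labels, counts))
    f_vals <- vapply(labels, function(lab) {
      r <- ranges[[lab]]
      stats::runif(1, r[1], r[2])
    }, numeric(1))
    trays <- lapply(seq_len(n_trays), function(t) {
      idx <- ((t - 1) * n_cells + 1):(t * n_cells)
      spec <- synth_spec(layout = layout, per_cell_f = f_vals[idx], seed = NULL, ...)
      generate_tray(spec)
    })
    # truth rows are row-major over cells, matching the per_cell_f layout
    truth <- dplyr::bind_rows(
      lapply(seq_len(n_trays), function(t) {
        dplyr::mutate(trays[[t]]$truth,
          tray = t,
          requested_label = labels[((t - 1) * n_cells + 1):(t * n_cells)],
          .before = 1
        )
      })
    )
    list(trays = trays, truth = truth)
  })
}

largest_remainder <- function(props, total) {
  raw <- props * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
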