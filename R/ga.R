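#' Genetic-algorithm settings for threshold search
#'
#' Defaults follow the settings used for pepper seedling trays: a population
#' of 21 chromosomes, at most 100 generations, single-point crossover with
#' probability 0.6 and per-bit mutation with probability 0.03. The search is
#' declared stable (and stops early) when the best fitness has not improved
#' for `stall_generations` consecutive generations.
#'
#' @param population_size Number of chromosomes per generation (>= 2).
#' @param max_generations Generation cap.
#' @param crossover_prob Probability a mated pair is crossed.
#' @param mutation_prob Per-bit flip probability.
#' @param stall_generations Early-stop patience on the best fitness.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 21L, max_generations = 100L,
                      crossover_prob = 0.6, mutation_prob = 0.03,
                      stall_generations = 20L, seed = NULL) {
  if (!is_scalar_number(population_size) || population_size < 2) {
    abort("`population_size` must be at least 2.")
  }
  for (p in list(crossover_prob, mutation_prob)) {
    if (!is_scalar_number(p) || p < 0 || p > 1) {
      abort("Crossover and mutation probabilities must lie in [0, 1].")
    }
  }
  if (!is_scalar_number(max_generations) || max_generations < 1) {
    abort("`max_generations` must be at least 1.")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      max_generations = as.integer(max_generations),
      crossover_prob = crossover_prob,
      mutation_prob = mutation_prob,
      stall_generations = as.integer(stall_generations),
      seed = seed
    ),
    class = "ga_config"
  )
}

#' Decode a 16-bit chromosome into a threshold pair
#'
#' The first eight bits encode `t1`, the remaining eight encode `t2` (most
#' significant bit first). Decoded pairs violating `t1 < t2` are repaired:
#' swap if out of order; if equal, increment `t2` modulo 256 and re-swap if
#' needed, so every 16-bit string maps to a feasible pair.
#'
#' @param bits A length-16 0/1 vector, or a 16-character string of 0s and 1s.
#' @return A list with integer `t1` and `t2`, `0 <= t1 < t2 <= 255`.
#' @examples
#' decode_chromosome("0101010110000000") # t1 = 85, t2 = 128
#' @export
decode_chromosome <- function(bits) {
  if (is.character(bits) && length(bits) == 1L) {
    bits <- as.integer(strsplit(bits, "")[[1]])
  }
  if (length(bits) != 16L || anyNA(bits) || !all(bits %in% c(0, 1))) {
    abort("A chromosome is exactly 16 binary digits.")
  }
  w <- 2^(7:0)
  t1 <- sum(bits[1:8] * w)
  t2 <- sum(bits[9:16] * w)
  repair_pair(t1, t2)
}

repair_pair <- function(t1, t2) {
  if (t1 > t2) {
    tmp <- t1
    t1 <- t2
    t2 <- tmp
  }
  if (t1 == t2) {
    t2 <- (t2 + 1) %% 256
    if (t1 > t2) {
      tmp <- t1
      t1 <- t2
      t2 <- tmp
    }
  }
  list(t1 = as.integer(t1), t2 = as.integer(t2))
}

#' Maximum-entropy threshold pair by genetic algorithm
#'
#' Optimizes the two-threshold entropy criterion of [entropy_fitness()] over
#' 16-bit chromosomes (8 bits per threshold). Each generation: fitness is
#' linearly scaled (mean preserved, maximum mapped to twice the mean, floored
#' at zero), parents are drawn by roulette-wheel selection, mated pairs
#' undergo single-point crossover keeping both offspring, and offspring bits
#' flip independently. One elite individual is copied unchanged each
#' generation and the best pair ever seen is returned, so the result is never
#' worse than the best of the initial population. The run stops at the
#' generation cap or when the best fitness stalls.
#'
#' @inheritParams entropy_fitness
#' @param config A [ga_config()].
#' @return A `ga_fit` object: list with `t1`, `t2`, `fitness`,
#'   `generations` run, and a per-generation `trace` tibble. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' h <- intensity_histogram(quantize_gray(matrix(rnorm(4096, 128, 40), 64), rescale = FALSE))
#' fit <- ga_thresholds(h, ga_config(seed = 1))
#' glance(fit)
#' @export
ga_thresholds <- function(hist, config = ga_config()) {
  p <- as_prob_vector(hist)
  if (!inherits(config, "ga_config")) {
    abort("`config` must be created with `ga_config()`.")
  }
  fit_fun <- make_fitness_lookup(p)
  n <- config$population_size

  with_seed(config$seed, {
    pop <- matrix(stats::rbinom(n * 16L, 1L, 0.5), nrow = n, ncol = 16L)
    best_bits <- NULL
    best_fit <- -Inf
    stall <- 0L
    trace <- vector("list", config$max_generations)
    gen <- 0L
    w <- 2^(7:0)

    repeat {
      gen <- gen + 1L
      t1 <- as.vector(pop[, 1:8] %*% w)
      t2 <- as.vector(pop[, 9:16] %*% w)
      fits <- vapply(seq_len(n), function(i) {
        pr <- repair_pair(t1[i], t2[i])
        fit_fun(pr$t1, pr$t2)
      }, numeric(1))

      gen_best <- max(fits)
      if (gen_best > best_fit + 1e-12) {
        best_fit <- gen_best
        best_bits <- pop[which.max(fits), ]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      trace[[gen]] <- c(generation = gen, best = max(gen_best, best_fit), mean = mean(fits))

      if (gen >= config$max_generations || stall >= config$stall_generations) {
        break
      }

      scaled <- scale_fitness(fits)
      elite <- pop[which.max(fits), , drop = FALSE]
      n_off <- n - 1L
      parents <- roulette_select(scaled, n_off + n_off %% 2L)
      offspring <- matrix(0L, nrow = length(parents), ncol = 16L)
      for (k in seq(1L, length(parents), by = 2L)) {
        a <- pop[parents[k], ]
        b <- pop[parents[k + 1L], ]
        if (stats::runif(1) < config$crossover_prob) {
          cut <- sample.int(15L, 1L)
          child_a <- c(a[seq_len(cut)], b[(cut + 1L):16L])
          child_b <- c(b[seq_len(cut)], a[(cut + 1L):16L])
        } else {
          child_a <- a
          child_b <- b
        }
        offspring[k, ] <- child_a
        offspring[k + 1L, ] <- child_b
      }
      offspring <- offspring[seq_len(n_off), , drop = FALSE]
      flips <- matrix(stats::runif(length(offspring)) < config$mutation_prob,
        nrow = nrow(offspring)
      )
      offspring <- (offspring + flips) %% 2L
      pop <- rbind(elite, offspring)
    }

    pair <- repair_pair(
      sum(best_bits[1:8] * w),
      sum(best_bits[9:16] * w)
    )
    structure(
      list(
        t1 = pair$t1, t2 = pair$t2, fitness = best_fit,
        generations = gen,
        trace = as_tibble(do.call(rbind, trace[seq_len(gen)])),
        config = config
      ),
      class = "ga_fit"
    )
  })
}

# O(1) pair fitness via prefix sums (same quantity as entropy_fitness()).
make_fitness_lookup <- function(p) {
  plogp <- ifelse(p > 0, p * log(p), 0)
  cp <- cumsum(p)
  cl <- cumsum(plogp)
  seg <- function(mass, s) {
    if (mass <= 0) 0 else log(mass) - s / mass
  }
  function(t1, t2) {
    m1 <- cp[t1 + 1L]
    m2 <- cp[t2 + 1L] - cp[t1 + 1L]
    m3 <- cp[256L] - cp[t2 + 1L]
    seg(m1, cl[t1 + 1L]) +
      seg(m2, cl[t2 + 1L] - cl[t1 + 1L]) +
      seg(m3, cl[256L] - cl[t2 + 1L])
  }
}

# Goldberg linear scaling: preserve the mean, map the max to twice the mean,
# floor at zero. Degenerate spreads fall back to uniform weights.
scale_fitness <- function(f) {
  favg <- mean(f)
  fmax <- max(f)
  if (fmax - favg < 1e-12 || favg <= 0) {
    return(rep(1, length(f)))
  }
  a <- favg / (fmax - favg)
  b <- favg * (fmax - 2 * favg) / (fmax - favg)
  pmax(a * f + b, 0)
}

roulette_select <- function(weights, k) {
  total <- sum(weights)
  if (total <= 0) {
    return(sample.int(length(weights), k, replace = TRUE))
  }
  cum <- cumsum(weights) / total
  findInterval(stats::runif(k), cum) + 1L
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf(
    "<ga_fit> thresholds (t1, t2) = (%d, %d), entropy = %.4f, %d generation(s)\n",
    x$t1, x$t2, x$fitness, x$generations
  ))
  invisible(x)
}

#' @rdname ga_thresholds
#' @param x,object A `ga_fit` object.
#' @param ... Unused.
#' @method tidy ga_fit
#' @export
tidy.ga_fit <- function(x, ...) {
  x$trace
}

#' @rdname ga_thresholds
#' @method glance ga_fit
#' @export
glance.ga_fit <- function(x, ...) {
  tibble(
    t1 = x$t1, t2 = x$t2, fitness = x$fitness,
    generations = x$generations
  )
}

#' @rdname ga_thresholds
#' @method autoplot ga_fit
#' @export
autoplot.ga_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$trace, c("best", "mean"),
    names_to = "series", values_to = "fitness"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$fitness, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Generation", y = "Entropy criterion",
      colour = NULL, title = "Genetic-algorithm threshold search"
    ) +
    ggplot2::theme_minimal()
}
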