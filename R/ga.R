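# Binary-coded genetic algorithm for selecting the incremental PID gains
# (GA-PID) or their initial values (GA-RBF-PID).
#
# Each individual carries one L-bit chromosome per gain. Fitness is the
# accumulated absolute tracking error J1 = sum_k |e(k)| of a closed-loop
# run; selection weights use 1/(1 + J1) so that minimisation of J1 becomes
# maximisation. Selection is stochastic universal sampling on rank-based
# weights with a generation gap: the top (1 - gap) fraction survives
# unchanged (elitism), the rest is replaced by offspring produced by
# single-point crossover (per gain) and independent bit-flip mutation.

#' GA configuration
#'
#' @param generations Number of generations (genetic algebra).
#' @param pop_size Population size (number of candidate gain triples).
#' @param chrom_length Bits per gain chromosome.
#' @param generation_gap Fraction of the population replaced each
#'   generation; the remaining top fraction is carried over unchanged.
#' @param crossover_rate Probability that a mating pair recombines (applied
#'   per gain chromosome).
#' @param mutation_rate Per-bit flip probability.
#' @param ranges 3 x 2 matrix of decoding ranges, rows Kp, Ki, Kd.
#' @param fitness_horizon Simulation duration (s) of each closed-loop
#'   fitness evaluation.
#' @param seed RNG seed of the evolution.
#' @return An object of class \code{"nm_ga_config"}.
#' @export
ga_config <- function(generations = 80L, pop_size = 50L, chrom_length = 20L,
                      generation_gap = 0.95, crossover_rate = 0.7,
                      mutation_rate = 0.01,
                      ranges = rbind(Kp = c(0, 1e7),
                                     Ki = c(0, 1e7),
                                     Kd = c(0, 2e6)),
                      fitness_horizon = 2, seed = 1L) {
  stopifnot(generations >= 1, pop_size >= 2, chrom_length >= 1,
            generation_gap > 0, generation_gap <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            is.matrix(ranges), nrow(ranges) == 3, ncol(ranges) == 2,
            all(is.finite(ranges)), all(ranges[, 2] > ranges[, 1]),
            fitness_horizon > 0)
  structure(list(generations = as.integer(generations),
                 pop_size = as.integer(pop_size),
                 chrom_length = as.integer(chrom_length),
                 generation_gap = generation_gap,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 ranges = ranges, fitness_horizon = fitness_horizon,
                 seed = as.integer(seed)),
            class = "nm_ga_config")
}

#' Decode a binary chromosome into a gain value
#'
#' Maps the integer value of an L-bit string linearly onto \code{[lo, hi]}:
#' \eqn{K = lo + \frac{\sum_j 2^{j-1}\beta_j}{2^L - 1}(hi - lo)}.
#' Bits are given most-significant first (as printed), so \code{"1000"}
#' with L = 4 decodes to \eqn{lo + 8/15 (hi - lo)}.
#'
#' @param bits 0/1 vector (or a string of 0s and 1s), most significant bit
#'   first.
#' @param lo,hi Decoding range.
#' @return Scalar in \code{[lo, hi]}.
#' @export
#' @examples
#' ga_decode("1000", 0, 15)  # 8
ga_decode <- function(bits, lo, hi) {
  if (is.character(bits)) {
    bits <- as.integer(strsplit(bits, "")[[1L]])
  }
  stopifnot(length(bits) >= 1, all(bits %in% c(0, 1)), hi > lo)
  L <- length(bits)
  val <- sum(bits * 2^((L:1) - 1))
  lo + val / (2^L - 1) * (hi - lo)
}

# decode all three chromosomes of one individual (a 3 x L 0/1 matrix)
decode_individual <- function(chrom, ranges) {
  vapply(1:3, function(j) ga_decode(chrom[j, ], ranges[j, 1], ranges[j, 2]),
         numeric(1))
}

#' Closed-loop fitness J1 of a gain triple
#'
#' Runs the scenario's closed loop with the candidate gains and returns the
#' accumulated absolute tracking error \eqn{J_1 = \sum_k |e(k)|} over the
#' horizon. A diverging loop yields a large finite penalty instead of an
#' error, so the evolution can continue past unstable candidates.
#'
#' @param gains Numeric length-3 vector (Kp, Ki, Kd).
#' @param sc An \code{\link{scenario}}; its controller type is ignored (the
#'   fixed-gain loop is evaluated).
#' @param horizon Evaluation duration (s); defaults to the scenario length.
#' @param penalty Fitness value assigned to diverging candidates.
#' @return J1 (non-negative scalar).
#' @export
ga_fitness <- function(gains, sc, horizon = NULL, penalty = 1e12) {
  stopifnot(inherits(sc, "nm_scenario"))
  sc$controller <- "ga_pid"
  sc$gains <- pid_gains(gains[1], gains[2], gains[3], allow_negative = TRUE)
  if (!is.null(horizon)) {
    sc$T <- horizon
    sc$gain_schedule <- sc$gain_schedule[sc$gain_schedule$time <= horizon, , drop = FALSE]
    w <- sc$control_windows
    if (is.vector(w)) w <- matrix(w, 1L, 2L)
    w <- w[w[, 1] < horizon, , drop = FALSE]
    w[, 2] <- pmin(w[, 2], horizon)
    sc$control_windows <- w
  }
  res <- tryCatch(run_scenario(sc), error = function(e) NULL)
  if (is.null(res)) {
    return(penalty)
  }
  err <- res$trace$ref - res$trace$y[, 1L]
  sel <- window_ids(res$trace$t, sc$control_windows) > 0L
  sum(abs(err[sel]))
}

# stochastic universal sampling: n picks proportional to w
sus_select <- function(w, n) {
  cum <- cumsum(w) / sum(w)
  start <- stats::runif(1) / n
  pts <- start + (seq_len(n) - 1L) / n
  findInterval(pts, cum, left.open = TRUE) + 1L
}

#' Evolve PID gains with the genetic algorithm
#'
#' Runs the binary-coded GA against a fitness function (by default the
#' closed-loop J1 of a scenario) and returns the best gains observed across
#' all generations together with the best-so-far convergence curve.
#'
#' @param cfg An \code{\link{ga_config}}.
#' @param fitness Function taking a length-3 numeric gain vector and
#'   returning J1 (lower is better). See \code{\link{ga_fitness}}.
#' @return A list of class \code{"nm_ga_fit"}: \code{gains} (an
#'   \code{\link{pid_gains}} object), \code{best_J1}, \code{curve}
#'   (best-so-far J1 per generation, non-increasing), \code{config}.
#' @export
#' @examples
#' # surrogate quadratic fitness with known optimum
#' cfg <- ga_config(generations = 30, pop_size = 20, chrom_length = 12,
#'                  ranges = rbind(c(0, 10), c(0, 10), c(0, 10)),
#'                  seed = 42)
#' fit <- ga_evolve(cfg, function(g) abs(g[1] - 7.3) + abs(g[2] - 2.5))
#' coef(fit)
ga_evolve <- function(cfg, fitness) {
  stopifnot(inherits(cfg, "nm_ga_config"), is.function(fitness))
  L <- cfg$chrom_length
  Qm <- cfg$pop_size
  with_seed(cfg$seed, {
    pop <- lapply(seq_len(Qm), function(i) {
      matrix(stats::rbinom(3L * L, 1L, 0.5), 3L, L)
    })
    best_J1 <- Inf
    best_gains <- NULL
    curve <- numeric(cfg$generations)
    n_keep <- max(1L, round((1 - cfg$generation_gap) * Qm))
    n_off <- Qm - n_keep

    for (gen in seq_len(cfg$generations)) {
      gains_all <- lapply(pop, decode_individual, ranges = cfg$ranges)
      J1 <- vapply(gains_all, fitness, numeric(1))
      gen_best <- which.min(J1)
      if (J1[gen_best] < best_J1) {
        best_J1 <- J1[gen_best]
        best_gains <- gains_all[[gen_best]]
      }
      curve[gen] <- best_J1
      if (gen == cfg$generations) break

      # rank-based selection weights on 1/(1+J1) ordering
      rnk <- rank(-J1, ties.method = "first")        # best -> highest rank
      w <- 2 * rnk / (Qm * (Qm + 1))
      parents <- sus_select(w, n_off)
      parents <- parents[sample.int(n_off)]          # shuffle pairing order

      offspring <- vector("list", n_off)
      i <- 1L
      while (i <= n_off) {
        p1 <- pop[[parents[i]]]
        p2 <- pop[[parents[if (i < n_off) i + 1L else 1L]]]
        c1 <- p1; c2 <- p2
        for (j in 1:3) {
          if (stats::runif(1) < cfg$crossover_rate && L > 1L) {
            cut <- sample.int(L - 1L, 1L)
            c1[j, ] <- c(p1[j, seq_len(cut)], p2[j, (cut + 1L):L])
            c2[j, ] <- c(p2[j, seq_len(cut)], p1[j, (cut + 1L):L])
          }
        }
        offspring[[i]] <- c1
        if (i + 1L <= n_off) offspring[[i + 1L]] <- c2
        i <- i + 2L
      }
      # bit-flip mutation
      offspring <- lapply(offspring, function(ch) {
        flip <- matrix(stats::runif(3L * L) < cfg$mutation_rate, 3L, L)
        ch[flip] <- 1L - ch[flip]
        ch
      })
      keep <- order(J1)[seq_len(n_keep)]             # elite survivors
      pop <- c(pop[keep], offspring)
    }
    structure(list(gains = pid_gains(best_gains[1], best_gains[2],
                                     best_gains[3], allow_negative = TRUE),
                   best_J1 = best_J1, curve = curve, config = cfg),
              class = "nm_ga_fit")
  })
}

#' @export
print.nm_ga_fit <- function(x, ...) {
  cat(sprintf("GA gain selection: %d generations x %d individuals (L = %d)\n",
              x$config$generations, x$config$pop_size, x$config$chrom_length))
  cat(sprintf("  best J1 = %.6g\n", x$best_J1))
  cat(sprintf("  gains: Kp = %.6g, Ki = %.6g, Kd = %.6g\n",
              x$gains[["Kp"]], x$gains[["Ki"]], x$gains[["Kd"]]))
  invisible(x)
}

#' @export
coef.nm_ga_fit <- function(object, ...) unclass(object$gains)

#' @export
plot.nm_ga_fit <- function(x, ...) {
  graphics::plot(seq_along(x$curve), x$curve, type = "s",
                 xlab = "generation", ylab = "best J1 so far",
                 main = "GA convergence", ...)
  invisible(x)
}
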