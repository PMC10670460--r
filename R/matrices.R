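#' Assemble the constant state-space matrices of one population
#'
#' Builds the matrices of the per-population state-space form
#' \deqn{\dot x = A x + B S(H x) + B_1 p + D \sum_m K_{ml} x_7^m,\quad y = C x.}
#' States come in four (signal, derivative) pairs driven by second-order
#' synaptic transfer blocks: (x1, x2) the excitatory feedback onto the
#' interneurons, (x3, x4) the excitatory input to the main cells, (x5, x6)
#' the inhibitory input to the main cells, and (x7, x8) the delayed
#' inter-population output. A is block-diagonal with companion blocks
#' \code{[[0, 1], [-mu^2, -2*mu]]}, mu = a, a, b, a_d. The output is
#' y = x3 - x5, the net membrane potential of the main cells.
#'
#' @param p A \code{\link{population_params}} object.
#' @return A list of class \code{"nm_matrices"} with elements \code{A} (8 x 8),
#'   \code{B} (8 x 3, one column per sigmoid channel), \code{B1} (length-8
#'   noise input map), \code{H} (3 x 8 sigmoid-argument map), \code{D}
#'   (length-8 coupling injection map) and \code{C} (1 x 8 output map).
#' @export
#' @examples
#' m <- assemble_matrices(population_params())
#' eigen(m$A)$values  # -a (x4), -b (x2), -a_d (x2)
assemble_matrices <- function(p) {
  stopifnot(inherits(p, "nm_population"))
  comp <- function(mu) matrix(c(0, -mu^2, 1, -2 * mu), 2, 2)
  A <- matrix(0, 8, 8)
  mus <- c(p$a, p$a, p$b, p$a_d)
  for (j in 1:4) {
    idx <- (2 * j - 1):(2 * j)
    A[idx, idx] <- comp(mus[j])
  }
  B <- matrix(0, 8, 3)
  B[2, 1] <- p$theta_A * p$a          # S(y) -> excitatory feedback block
  B[8, 1] <- p$theta_A * p$a_d        # S(y) -> delayed inter-population block
  B[4, 2] <- p$theta_A * p$a * p$c2   # S(c1 x1) -> main-cell excitatory input
  B[6, 3] <- p$theta_B * p$b * p$c4   # S(c3 x1) -> main-cell inhibitory input
  B1 <- numeric(8)
  B1[4] <- p$theta_A * p$a
  H <- matrix(0, 3, 8)
  H[1, 3] <- 1; H[1, 5] <- -1         # y = x3 - x5
  H[2, 1] <- p$c1
  H[3, 1] <- p$c3
  D <- numeric(8)
  D[4] <- 1
  C <- matrix(0, 1, 8)
  C[1, 3] <- 1; C[1, 5] <- -1
  structure(list(A = A, B = B, B1 = B1, H = H, D = D, C = C),
            class = "nm_matrices")
}

# Precompute per-population dynamics constants as N-vectors so the
# derivative can be evaluated for all populations at once.
# theta_A_noise optionally pins the afferent-noise channel gain (B1) to a
# value different from the sigmoid-channel gain theta_A, so that a gain
# mutation can act on the synaptic feedback loops while the noise drive
# keeps the normal-regime gain.
dyn_consts <- function(populations, theta_A_noise = NULL) {
  g <- function(f) vapply(populations, function(p) f(p), numeric(1))
  sig <- populations[[1L]]$sigmoid
  thAn <- if (is.null(theta_A_noise)) {
    g(function(p) p$theta_A)
  } else {
    rep_len(theta_A_noise, length(populations))
  }
  list(
    thAn_a = thAn * g(function(p) p$a),
    a     = g(function(p) p$a),
    b     = g(function(p) p$b),
    ad    = g(function(p) p$a_d),
    a2    = g(function(p) p$a^2),
    b2    = g(function(p) p$b^2),
    ad2   = g(function(p) p$a_d^2),
    twoa  = g(function(p) 2 * p$a),
    twob  = g(function(p) 2 * p$b),
    twoad = g(function(p) 2 * p$a_d),
    thAa  = g(function(p) p$theta_A * p$a),
    thAad = g(function(p) p$theta_A * p$a_d),
    c2    = g(function(p) p$c2),
    c1    = g(function(p) p$c1),
    c3    = g(function(p) p$c3),
    thBbc4 = g(function(p) p$theta_B * p$b * p$c4),
    twoe0 = 2 * sig$e0, v0 = sig$v0, r = sig$r
  )
}

# Vectorised derivative over all populations. X is 8 x N, pn length N,
# u scalar, fpop length-N 0/1 selector of controlled populations.
deriv_fast <- function(X, pn, u, dc, K, fpop) {
  s <- function(v) {
    z <- pmin(pmax(dc$r * (dc$v0 - v), -700), 700)
    dc$twoe0 / (1 + exp(z))
  }
  s1 <- s(X[3, ] - X[5, ])
  s2 <- s(dc$c1 * X[1, ])
  s3 <- s(dc$c3 * X[1, ])
  coup <- colSums(K * X[7, ])
  dX <- X
  dX[1, ] <- X[2, ]
  dX[2, ] <- dc$thAa * s1 - dc$twoa * X[2, ] - dc$a2 * X[1, ]
  dX[3, ] <- X[4, ]
  dX[4, ] <- dc$thAn_a * pn + dc$thAa * dc$c2 * s2 + coup + fpop * u -
    dc$twoa * X[4, ] - dc$a2 * X[3, ]
  dX[5, ] <- X[6, ]
  dX[6, ] <- dc$thBbc4 * s3 - dc$twob * X[6, ] - dc$b2 * X[5, ]
  dX[7, ] <- X[8, ]
  dX[8, ] <- dc$thAad * s1 - dc$twoad * X[8, ] - dc$ad2 * X[7, ]
  dX
}

#' Time derivative of the coupled model state
#'
#' Evaluates the right-hand side of the coupled model for the full 8N state:
#' per-population linear dynamics, sigmoid feedback, noise drive, the
#' coupling term (the delayed signal x7 of every other population, weighted
#' by K and injected into the excitatory-input row) and the additive external
#' control F u.
#'
#' @param x State vector of length 8N.
#' @param p_noise Drive value for each population (length N).
#' @param u Scalar external control input.
#' @param cfg A \code{\link{coupled_model_config}}.
#' @param F_map Length-8N 0/1 vector selecting the rows that receive u;
#'   default places a 1 in the x4-dot row of every population.
#' @return The length-8N time derivative.
#' @export
nm_derivative <- function(x, p_noise, u = 0, cfg, F_map = default_F(cfg$N)) {
  stopifnot(length(x) == 8L * cfg$N, length(p_noise) == cfg$N,
            length(F_map) == 8L * cfg$N)
  dc <- dyn_consts(cfg$populations)
  X <- matrix(x, 8L, cfg$N)
  fpop <- F_map[seq(4L, by = 8L, length.out = cfg$N)]
  as.vector(deriv_fast(X, p_noise, u, dc, cfg$K, fpop))
}

#' Default control input map
#'
#' A length-8N 0/1 vector with a 1 in the excitatory-input (x4-dot) row of
#' each controlled population; by default every population is controlled,
#' matching a model in which all populations are hyperexcited.
#'
#' @param N Number of populations.
#' @param controlled Integer indices of the populations receiving the control
#'   input.
#' @return A numeric 0/1 vector of length 8N.
#' @export
default_F <- function(N, controlled = seq_len(N)) {
  f <- numeric(8L * N)
  f[8L * (controlled - 1L) + 4L] <- 1
  f
}

#' One classical fourth-order Runge-Kutta step
#'
#' Advances the coupled model state by one step of size \code{dt}, holding
#' the noise drive and the control input constant over the step (the white
#' noise is interpreted as piecewise constant across the four substeps).
#'
#' @inheritParams nm_derivative
#' @param dt Step size (s).
#' @return The state after one step.
#' @export
rk4_step <- function(x, p_noise, u = 0, dt, cfg, F_map = default_F(cfg$N)) {
  stopifnot(dt > 0)
  dc <- dyn_consts(cfg$populations)
  X <- matrix(x, 8L, cfg$N)
  fpop <- F_map[seq(4L, by = 8L, length.out = cfg$N)]
  k1 <- deriv_fast(X, p_noise, u, dc, cfg$K, fpop)
  k2 <- deriv_fast(X + (dt / 2) * k1, p_noise, u, dc, cfg$K, fpop)
  k3 <- deriv_fast(X + (dt / 2) * k2, p_noise, u, dc, cfg$K, fpop)
  k4 <- deriv_fast(X + dt * k3, p_noise, u, dc, cfg$K, fpop)
  out <- X + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  if (!all(is.finite(out))) {
    stop("non-finite state after RK4 step", call. = FALSE)
  }
  as.vector(out)
}
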