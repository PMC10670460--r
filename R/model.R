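#' Sigmoid (firing-rate) parameters
#'
#' Parameters of the static non-linearity converting mean membrane potential
#' (mV) into mean firing rate (s^-1): \eqn{S(v) = 2 e_0 / (1 + e^{r (v_0 - v)})}.
#'
#' @param e0 Half of the maximum firing rate (s^-1); the curve saturates at
#'   \code{2 * e0}.
#' @param v0 Potential at which half the maximum rate is reached (mV).
#' @param r Steepness of the sigmoid (mV^-1).
#' @return An object of class \code{"nm_sigmoid"}.
#' @export
#' @examples
#' sp <- sigmoid_params()
#' sigmoid(6, sp)  # equals e0 at v = v0
sigmoid_params <- function(e0 = 2.5, v0 = 6, r = 0.56) {
  stopifnot(is_number(e0), is_number(v0), is_number(r), e0 > 0, r > 0)
  structure(list(e0 = e0, v0 = v0, r = r), class = "nm_sigmoid")
}

#' Firing-rate sigmoid
#'
#' Evaluates \eqn{S(v) = 2 e_0 / (1 + e^{r (v_0 - v)})}, the population
#' wave-to-pulse conversion. Strictly increasing, with range \eqn{(0, 2 e_0)}.
#' The exponent is clamped at +/-700 so the value stays inside the open
#' interval for arbitrarily large |v| instead of overflowing.
#'
#' @param v Membrane potential(s), mV. Vectorised.
#' @param sp A \code{\link{sigmoid_params}} object.
#' @return Firing rate(s), s^-1.
#' @export
sigmoid <- function(v, sp = sigmoid_params()) {
  z <- sp$r * (sp$v0 - v)
  z <- pmin(pmax(z, -700), 700)
  2 * sp$e0 / (1 + exp(z))
}

#' Physiological parameters of one neural population
#'
#' Lumped constants of a single Wendling-type population: synaptic gains,
#' membrane/dendritic rate constants, the inter-population contact rate, the
#' four intrinsic connectivity constants and the firing-rate sigmoid. The
#' defaults are the standard values under which the population produces a
#' well-defined alpha-like (8-13 Hz) oscillation; raising \code{theta_A}
#' to about 3.5 mV drives it into high-amplitude spiking.
#'
#' @param theta_A Average excitatory synaptic gain (mV). Standard 3.25.
#' @param theta_B Average inhibitory synaptic gain (mV). Standard 22.
#' @param a Excitatory rate constant (s^-1). Standard 100.
#' @param b Inhibitory rate constant (s^-1). Standard 50.
#' @param a_d Inter-population contact rate constant (s^-1). Standard 33.
#' @param c1,c2 Connectivity constants of the excitatory feedback loop.
#' @param c3,c4 Connectivity constants of the inhibitory feedback loop.
#' @param sigmoid A \code{\link{sigmoid_params}} object.
#' @return An object of class \code{"nm_population"}.
#' @seealso \code{\link{delta_population_params}} for the delta-regime set.
#' @export
population_params <- function(theta_A = 3.25, theta_B = 22,
                              a = 100, b = 50, a_d = 33,
                              c1 = 135, c2 = 108, c3 = 33.75, c4 = 33.75,
                              sigmoid = sigmoid_params()) {
  stopifnot(
    is_number(theta_A), is_number(theta_B), theta_A > 0, theta_B > 0,
    is_number(a), is_number(b), is_number(a_d), a > 0, b > 0, a_d > 0,
    is_number(c1), is_number(c2), is_number(c3), is_number(c4),
    c1 >= 0, c2 >= 0, c3 >= 0, c4 >= 0,
    inherits(sigmoid, "nm_sigmoid")
  )
  structure(list(theta_A = theta_A, theta_B = theta_B, a = a, b = b,
                 a_d = a_d, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 sigmoid = sigmoid),
            class = "nm_population")
}

#' Delta-regime population parameters
#'
#' Parameter set under which the population produces a delta-like (< 4 Hz)
#' oscillation, used as the expected output in the sleep-state experiments:
#' theta_A = 2 mV, theta_B = 15 mV, a = b = 20 s^-1, a_d = 33 s^-1, with the
#' standard connectivity and sigmoid constants.
#'
#' @param theta_A Excitatory gain (mV); defaults to the delta-regime value 2.
#' @return An \code{"nm_population"} object.
#' @export
delta_population_params <- function(theta_A = 2) {
  population_params(theta_A = theta_A, theta_B = 15, a = 20, b = 20, a_d = 33)
}

#' Gaussian white-noise drive specification
#'
#' The afferent pulse density p(t) of each population is modelled as Gaussian
#' white noise, drawn once per integration step and held constant across the
#' Runge-Kutta substeps.
#'
#' @param mean Mean pulse density (dimensionless drive units).
#' @param sd Standard deviation of the drive.
#' @param seed Integer RNG seed making the realisation reproducible.
#' @return An object of class \code{"nm_noise"}.
#' @export
noise_spec <- function(mean = 101, sd = 35, seed = 1L) {
  stopifnot(is_number(mean), is_number(sd), sd >= 0, is_number(seed))
  structure(list(mean = mean, sd = sd, seed = as.integer(seed)),
            class = "nm_noise")
}

#' Coupled neural mass model configuration
#'
#' Assembles N populations, their coupling matrix, the noise drive and the
#' integration settings into a single simulatable model. Each population
#' carries 8 state variables (four second-order synaptic transfer blocks),
#' so the full state has dimension 8N. Population m influences population l
#' through the delayed inter-population signal x7 of m, weighted by
#' \code{K[m, l]} and injected into the excitatory-input row (x4-dot) of l.
#'
#' @param N Number of populations. The coupled formulation is intended for
#'   N > 2; smaller N is accepted with a warning to ease unit testing.
#' @param populations A single \code{\link{population_params}} object (reused
#'   for all populations) or a list of N of them.
#' @param K Coupling: either a scalar (uniform all-to-all strength, zero
#'   diagonal) or a full N x N non-negative matrix with zero diagonal.
#'   \code{K[m, l]} weights the influence of population m on population l.
#' @param noise A \code{\link{noise_spec}} object.
#' @param dt Integration/sampling step (s).
#' @param x0 Initial 8N state vector; default all zeros.
#' @return An object of class \code{"nm_model"}.
#' @export
#' @examples
#' cfg <- coupled_model_config(N = 3, K = 28)
#' tr <- simulate_open_loop(cfg, T = 2)
coupled_model_config <- function(N = 3, populations = population_params(),
                                 K = 28, noise = noise_spec(), dt = 0.001,
                                 x0 = NULL) {
  stopifnot(is_number(N), N >= 1, N == round(N), is_number(dt), dt > 0,
            inherits(noise, "nm_noise"))
  N <- as.integer(N)
  if (N <= 2) {
    warning("the coupled model is intended for N > 2 populations; ",
            "proceeding with N = ", N, call. = FALSE)
  }
  if (inherits(populations, "nm_population")) {
    populations <- rep(list(populations), N)
  }
  stopifnot(length(populations) == N,
            all(vapply(populations, inherits, logical(1), "nm_population")))
  if (is.matrix(K)) {
    stopifnot(nrow(K) == N, ncol(K) == N, all(K >= 0), all(diag(K) == 0))
  } else {
    stopifnot(is_number(K), K >= 0)
    K <- matrix(K, N, N) - diag(rep(K, N), N)
  }
  if (is.null(x0)) x0 <- numeric(8L * N)
  stopifnot(length(x0) == 8L * N, all(is.finite(x0)))
  structure(list(N = N, populations = populations, K = K, noise = noise,
                 dt = dt, x0 = x0),
            class = "nm_model")
}

#' @export
print.nm_model <- function(x, ...) {
  p1 <- x$populations[[1L]]
  cat(sprintf("Coupled neural mass model: N = %d populations, dt = %g s\n",
              x$N, x$dt))
  cat(sprintf("  population 1: theta_A = %g mV, theta_B = %g mV, a = %g, b = %g, a_d = %g s^-1\n",
              p1$theta_A, p1$theta_B, p1$a, p1$b, p1$a_d))
  cat(sprintf("  coupling: max K = %g; noise: mean %g, sd %g, seed %d\n",
              max(x$K), x$noise$mean, x$noise$sd, x$noise$seed))
  invisible(x)
}
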