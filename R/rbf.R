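# RBF-network plant estimator and online PID gain adaptation.
#
# The network is a single hidden layer of Gaussian kernels
# xi_j = exp(-||x - eps_j||^2 / (2 theta_j^2)) with a linear output
# y_hat = sum_j w_j xi_j. It estimates the controlled output from the
# first population's states plus the control input, and its analytic
# Jacobian d y_hat / d u drives the online adaptation of the PID gains.

# -- raw kernels shared by the public API and the simulation loop ---------

rbf_forward_raw <- function(centers, widths, weights, xr) {
  d2 <- colSums((t(centers) - xr)^2)
  xi <- exp(-d2 / (2 * widths^2))
  list(y = sum(weights * xi), xi = xi, d2 = d2)
}

# derivative of y_hat with respect to the last input coordinate
rbf_jacobian_raw <- function(centers, widths, weights, xr, xi) {
  M <- length(xr)
  -sum(weights * xi * (xr[M] - centers[, M]) / widths^2)
}

# gradient-descent corrections (without the momentum terms)
rbf_update_raw <- function(centers, widths, weights, xr, xi, err, eta) {
  wxi <- weights * xi
  d2 <- colSums((t(centers) - xr)^2)
  list(
    dw  = eta * err * xi,
    dth = eta * err * wxi * d2 / widths^3,
    dc  = eta * err * (wxi / widths^2) * (matrix(xr, nrow(centers),
                                                 length(xr), byrow = TRUE) - centers)
  )
}

#' RBF estimator / adaptation configuration
#'
#' Hyper-parameters of the RBF plant estimator and of the online PID gain
#' adaptation. Inputs are normalised before entering the Gaussian kernels:
#' the population states are multiplied by \code{state_scale} and the control
#' coordinate is divided by the largest |u| seen so far (floored at 1), so
#' that kernels keep discriminating between inputs whose raw magnitudes
#' differ by six orders.
#'
#' @param H Number of hidden nodes.
#' @param M Input dimension; 9 = the eight states of the feedback population
#'   plus the control input.
#' @param eta Estimator learning rate for weights, centers and widths.
#' @param alpha Momentum (inertia) coefficient in [0, 1).
#' @param eta_p,eta_i,eta_d Learning rates of the proportional, integral and
#'   differential gain adaptation.
#' @param state_scale Multiplicative normalisation of the state inputs:
#'   a scalar or a length M-1 vector (one constant per state coordinate).
#'   The default for the 9-input experiment layout maps typical
#'   alpha-regime amplitudes of the potentials (x1, x3, x5, x7) and their
#'   derivatives (x2, x4, x6, x8) into roughly [-1, 1]; for other M the
#'   default is 1.
#' @param gain_step_frac Cap on each per-step gain change as a fraction of
#'   the current gain magnitude (NULL disables the cap).
#' @param width_init Initial kernel width (shared by all hidden nodes).
#' @param u_compress Extra attenuation of the control coordinate entering
#'   the kernels: u is divided by \code{u_compress} times the running
#'   max-|u| normalisation. Values > 1 keep the per-step jitter of u from
#'   dominating the kernel distances (the Jacobian chain rule accounts for
#'   it).
#' @param width_floor Lower bound keeping kernel widths strictly positive.
#' @return An object of class \code{"nm_rbf_config"}.
#' @export
rbf_config <- function(H = 6L, M = 9L, eta = 0.5, alpha = 0.05,
                       eta_p = 1e12, eta_i = 1e12, eta_d = 1e12,
                       state_scale = NULL,
                       gain_step_frac = 0.01, width_init = 1,
                       u_compress = 1, width_floor = 1e-3,
                       always_train = FALSE) {
  if (is.null(state_scale)) {
    state_scale <- if (M == 9L) c(2, 0.2, 0.1, 0.01, 0.1, 0.01, 2, 0.2) else 1
  }
  stopifnot(H >= 1, M >= 2, eta >= 0, alpha >= 0, alpha < 1,
            eta_p >= 0, eta_i >= 0, eta_d >= 0,
            all(state_scale > 0), length(state_scale) %in% c(1L, M - 1L),
            width_init > 0, u_compress >= 1, width_floor > 0)
  state_scale <- rep_len(state_scale, M - 1L)
  structure(list(H = as.integer(H), M = as.integer(M), eta = eta,
                 alpha = alpha, eta_p = eta_p, eta_i = eta_i, eta_d = eta_d,
                 state_scale = state_scale, gain_step_frac = gain_step_frac,
                 width_init = width_init, u_compress = u_compress,
                 width_floor = width_floor, always_train = always_train),
            class = "nm_rbf_config")
}

#' Initialise an RBF network
#'
#' Centers are sampled uniformly over the scaled input hypercube [-1, 1]^M,
#' widths start at 1 and output weights at 0, so the initial estimate is
#' identically zero and training starts from a neutral state.
#'
#' @param cfg An \code{\link{rbf_config}}.
#' @param seed RNG seed for the center draw.
#' @return An object of class \code{"nm_rbf"} with fields \code{centers}
#'   (H x M), \code{widths} (length H) and \code{weights} (length H).
#' @export
rbf_network <- function(cfg = rbf_config(), seed = 1L) {
  centers <- with_seed(seed,
                       matrix(stats::runif(cfg$H * cfg$M, -1, 1), cfg$H, cfg$M))
  structure(list(centers = centers, widths = rep(cfg$width_init, cfg$H),
                 weights = rep(0, cfg$H), cfg = cfg),
            class = "nm_rbf")
}

#' RBF forward pass
#'
#' Evaluates the Gaussian hidden activations and the network output for one
#' (already scaled) input vector.
#'
#' @param net An \code{\link{rbf_network}}.
#' @param xr Input vector of length M, scaled per the network's config.
#' @return A list with \code{y} (the scalar estimate) and \code{xi} (the
#'   hidden activations, each in (0, 1]).
#' @export
rbf_forward <- function(net, xr) {
  stopifnot(inherits(net, "nm_rbf"), length(xr) == ncol(net$centers))
  if (!all(is.finite(xr))) stop("non-finite RBF input", call. = FALSE)
  fw <- rbf_forward_raw(net$centers, net$widths, net$weights, xr)
  fw[c("y", "xi")]
}

#' One gradient-descent training step of the RBF estimator
#'
#' Minimises \eqn{J_2 = (y - \hat y)^2 / 2} by a gradient step on the output
#' weights, kernel widths and centers, each with a momentum term
#' \eqn{\alpha (\vartheta(k-1) - \vartheta(k-2))}. Widths are floored at
#' \code{width_floor} to stay strictly positive. A step that would produce
#' non-finite parameters is skipped and the network returned unchanged.
#'
#' @param net An \code{\link{rbf_network}}; its \code{prev} field (if any)
#'   holds the previous parameter values used by the momentum terms.
#' @param xr Scaled input vector.
#' @param y_true Measured plant output (mV).
#' @return A list with \code{net} (updated network), \code{y_hat} (the
#'   pre-update estimate) and \code{err} (\code{y_true - y_hat}).
#' @export
rbf_train_step <- function(net, xr, y_true) {
  stopifnot(inherits(net, "nm_rbf"))
  fw <- rbf_forward_raw(net$centers, net$widths, net$weights, xr)
  err <- y_true - fw$y
  cfg <- net$cfg
  prev <- if (is.null(net$prev)) {
    list(centers = net$centers, widths = net$widths, weights = net$weights)
  } else {
    net$prev
  }
  up <- rbf_update_raw(net$centers, net$widths, net$weights, xr, fw$xi,
                       err, cfg$eta)
  new_w <- net$weights + up$dw + cfg$alpha * (net$weights - prev$weights)
  new_th <- net$widths + up$dth + cfg$alpha * (net$widths - prev$widths)
  new_c <- net$centers + up$dc + cfg$alpha * (net$centers - prev$centers)
  if (all(is.finite(new_w)) && all(is.finite(new_th)) && all(is.finite(new_c))) {
    net$prev <- list(centers = net$centers, widths = net$widths,
                     weights = net$weights)
    net$weights <- new_w
    net$widths <- pmax(new_th, cfg$width_floor)
    net$centers <- new_c
  } else {
    warning("non-finite RBF update skipped", call. = FALSE)
  }
  list(net = net, y_hat = fw$y, err = err)
}

#' Jacobian of the RBF estimate with respect to the control input
#'
#' Analytic partial derivative of the network output with respect to the
#' last input coordinate (the control input):
#' \eqn{\partial \hat y / \partial u = -\sum_j w_j \xi_j (u - \varepsilon_{jM}) / \theta_j^2}.
#' When the control coordinate entering the network is a scaled version of
#' the raw input, pass the scale so the chain rule converts the derivative
#' back to raw control units.
#'
#' @param net An \code{\link{rbf_network}}.
#' @param xr Scaled input vector.
#' @param u_scale Derivative of the scaled control coordinate with respect
#'   to the raw control input (chain-rule factor; default 1).
#' @return The scalar Jacobian estimate.
#' @export
rbf_jacobian <- function(net, xr, u_scale = 1) {
  stopifnot(inherits(net, "nm_rbf"), length(xr) == ncol(net$centers))
  fw <- rbf_forward_raw(net$centers, net$widths, net$weights, xr)
  rbf_jacobian_raw(net$centers, net$widths, net$weights, xr, fw$xi) * u_scale
}

#' Online adaptation of the PID gains
#'
#' Gradient step on the estimator cost with respect to each gain, using the
#' RBF Jacobian in place of the unknown plant sensitivity:
#' \eqn{\Delta K_p = -\eta_p (y - \hat y) (\partial \hat y / \partial u) e_2}
#' and analogously for \eqn{K_i} (with \eqn{e_1 = e}) and \eqn{K_d} (with
#' \eqn{e_3}). Each change is optionally capped at
#' \code{gain_step_frac} of the current gain magnitude.
#'
#' @param g An \code{\link{pid_gains}} object.
#' @param jac Jacobian estimate \eqn{\partial \hat y / \partial u}.
#' @param est_err Estimation error \eqn{y - \hat y} (mV).
#' @param errs Length-3 vector \code{c(e1, e2, e3)}: the error, its first
#'   difference and its second difference.
#' @param cfg An \code{\link{rbf_config}}.
#' @return The updated \code{"nm_pid_gains"} object.
#' @export
adapt_pid_gains <- function(g, jac, est_err, errs, cfg) {
  stopifnot(length(errs) == 3L, all(is.finite(c(jac, est_err, errs))))
  dK <- -c(cfg$eta_p, cfg$eta_i, cfg$eta_d) * est_err * jac *
    c(errs[2L], errs[1L], errs[3L])
  if (!is.null(cfg$gain_step_frac)) {
    cap <- cfg$gain_step_frac * abs(unclass(g))
    dK <- pmin(pmax(dK, -cap), cap)
  }
  structure(unclass(g) + dK, class = "nm_pid_gains")
}

#' Run the RBF-adaptive (GA-RBF-PID) closed loop
#'
#' Same loop as \code{\link{run_closed_loop}}, but inside each control
#' window the RBF estimator is trained online against the measured feedback
#' output and its Jacobian with respect to the control input adapts the PID
#' gains at every step. With all adaptation rates zero the trajectory is
#' identical to the fixed-gain loop started from \code{g0}.
#'
#' @inheritParams run_closed_loop
#' @param g0 Initial PID gains (typically GA-selected).
#' @param rbf_cfg An \code{\link{rbf_config}}.
#' @param rbf_seed Seed for the RBF center initialisation.
#' @return An \code{"nm_trace"} with additional per-step series: \code{gains}
#'   (n x 3), \code{yhat} (estimator output), \code{J2} (estimator cost) and
#'   the final network in \code{rbf_net}.
#' @export
run_ga_rbf_pid <- function(cfg, ctrl, g0, rbf_cfg = rbf_config(), ref, T,
                           noise = NULL, schedule = NULL, rbf_seed = 1L,
                           keep_states = TRUE, theta_A_noise = NULL) {
  stopifnot(inherits(ctrl, "nm_control"), inherits(g0, "nm_pid_gains"),
            inherits(rbf_cfg, "nm_rbf_config"))
  net <- rbf_network(rbf_cfg, seed = rbf_seed)
  sim_loop(cfg, T, noise = noise, schedule = schedule,
           controller = list(type = "rbf", gains = unclass(g0), ctrl = ctrl,
                             rbf_cfg = rbf_cfg, rbf_net = net),
           ref = ref, keep_states = keep_states,
           theta_A_noise = theta_A_noise)
}
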