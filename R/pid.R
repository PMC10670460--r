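#' PID gains
#'
#' The three coefficients of the incremental PID law, mapping the tracking
#' error (mV) to increments of the external control input (drive units).
#'
#' @param Kp Proportional coefficient (acts on the first error difference).
#' @param Ki Integral coefficient (acts on the error itself).
#' @param Kd Differential coefficient (acts on the second error difference).
#' @param allow_negative Permit negative coefficients (off by default).
#' @return An object of class \code{"nm_pid_gains"} (a named numeric vector).
#' @export
#' @examples
#' ga_pid_printed_gains()
pid_gains <- function(Kp, Ki, Kd, allow_negative = FALSE) {
  g <- c(Kp = Kp, Ki = Ki, Kd = Kd)
  stopifnot(all(is.finite(g)))
  if (!allow_negative && any(g < 0)) {
    stop("PID gains must be non-negative (set allow_negative = TRUE to override)",
         call. = FALSE)
  }
  structure(g, class = "nm_pid_gains")
}

#' GA-selected gains for the fixed-gain experiments
#'
#' The incremental PID gains selected offline by the genetic algorithm for
#' the GA-PID scheme, and the initial gains it selects for the GA-RBF-PID
#' scheme.
#'
#' @return An \code{"nm_pid_gains"} object.
#' @export
ga_pid_printed_gains <- function() {
  pid_gains(Kp = 4501999.99, Ki = 2029999.77, Kd = 459999.99)
}

#' @rdname ga_pid_printed_gains
#' @export
ga_rbf_pid_printed_gains <- function() {
  pid_gains(Kp = 9494942.85, Ki = 5999712.96, Kd = 1499968.47)
}

#' Incremental PID state
#'
#' The memory of the incremental law: the previous control input and the two
#' previous control errors. Initialised to zero at every control onset.
#'
#' @param u_prev Previous control input.
#' @param e_prev1,e_prev2 The two most recent control errors (mV).
#' @return An object of class \code{"nm_pid_state"}.
#' @export
pid_state <- function(u_prev = 0, e_prev1 = 0, e_prev2 = 0) {
  structure(list(u_prev = u_prev, e_prev1 = e_prev1, e_prev2 = e_prev2),
            class = "nm_pid_state")
}

#' One increment of the incremental PID law
#'
#' Computes \eqn{\Delta u = K_p (e - e_1) + K_i e + K_d (e - 2 e_1 + e_2)}
#' where \eqn{e_1, e_2} are the two previous errors, and shifts the error
#' history.
#'
#' @param e Current control error (mV).
#' @param st A \code{\link{pid_state}}.
#' @param g A \code{\link{pid_gains}} object.
#' @return A list with \code{du} (the control increment), \code{u} (the
#'   updated control input \code{st$u_prev + du}) and \code{state} (the
#'   shifted \code{nm_pid_state}).
#' @export
#' @examples
#' st <- pid_state(e_prev1 = 2, e_prev2 = 0)
#' pid_increment(3, st, pid_gains(1, 2, 3))$du  # 1*1 + 2*3 + 3*(3-4+0) = 4
pid_increment <- function(e, st, g) {
  if (!is.finite(e)) stop("non-finite control error", call. = FALSE)
  du <- g[["Kp"]] * (e - st$e_prev1) + g[["Ki"]] * e +
    g[["Kd"]] * (e - 2 * st$e_prev1 + st$e_prev2)
  u <- st$u_prev + du
  list(du = du, u = u,
       state = pid_state(u_prev = u, e_prev1 = e, e_prev2 = st$e_prev1))
}

#' Closed-loop control configuration
#'
#' Where and when the external control acts: the state rows receiving the
#' input (the excitatory-input row of each controlled population), the output
#' component fed back, and the time windows during which the loop is closed.
#' The PID state is reset at each window onset and the input is zero outside
#' the windows.
#'
#' @param N Number of populations of the controlled model.
#' @param windows Numeric k x 2 matrix (or length-2 vector) of
#'   \code{[start, end)} control windows in seconds; must be sorted and
#'   non-overlapping.
#' @param controlled Indices of the populations receiving the control input
#'   (default all, matching a fully hyperexcited model).
#' @param feedback_population Index of the population whose output forms the
#'   control error (default 1).
#' @param u_limit Optional symmetric saturation bound on u (default none).
#' @param n_sub Internal RK4 substeps per sampling step while control is
#'   active. The default 2 keeps the fast closed-loop crossover modes of
#'   gain sets up to ~1e7 inside the integrator's stability region;
#'   \code{n_sub = 1} integrates controlled and uncontrolled steps
#'   identically (so a zero-gain loop reproduces the open-loop trace
#'   bit for bit).
#' @return An object of class \code{"nm_control"}.
#' @export
control_config <- function(N = 3, windows, controlled = seq_len(N),
                           feedback_population = 1L, u_limit = NULL,
                           n_sub = 2L) {
  if (is.vector(windows) && length(windows) == 2L) {
    windows <- matrix(windows, 1L, 2L)
  }
  stopifnot(is.matrix(windows), ncol(windows) == 2L,
            all(windows[, 2L] > windows[, 1L]))
  if (nrow(windows) > 1L) {
    o <- order(windows[, 1L])
    windows <- windows[o, , drop = FALSE]
    stopifnot(all(windows[-1L, 1L] >= windows[-nrow(windows), 2L]))
  }
  if (!is.null(u_limit)) stopifnot(is_number(u_limit), u_limit >= 0)
  stopifnot(n_sub >= 1)
  structure(list(windows = windows, F_map = default_F(N, controlled),
                 feedback_population = as.integer(feedback_population),
                 u_limit = u_limit, n_sub = as.integer(n_sub)),
            class = "nm_control")
}

#' Run the incremental PID closed loop
#'
#' Simulates the controlled model with the incremental PID law around it.
#' Inside each control window the error \eqn{e(k) = r(k) - y_b(k)} is formed
#' from the feedback population's output, the control input is updated by
#' \code{\link{pid_increment}}, and the plant is stepped with the input
#' injected into the excitatory-input row of every controlled population.
#' Outside the windows the input is zero; the PID state is re-initialised at
#' every window onset.
#'
#' @param cfg A \code{\link{coupled_model_config}} for the controlled plant.
#' @param ctrl A \code{\link{control_config}}.
#' @param g A \code{\link{pid_gains}} object.
#' @param ref Reference sequence r(k), length at least \code{floor(T/dt)+1}.
#' @param T Duration (s).
#' @param noise Optional pre-drawn noise matrix shared with the reference.
#' @param schedule Optional excitatory-gain schedule (see
#'   \code{\link{simulate_open_loop}}).
#' @param keep_states Keep the full state trajectory.
#' @return An \code{"nm_trace"} object.
#' @export
run_closed_loop <- function(cfg, ctrl, g, ref, T, noise = NULL,
                            schedule = NULL, keep_states = TRUE,
                            theta_A_noise = NULL) {
  stopifnot(inherits(ctrl, "nm_control"), inherits(g, "nm_pid_gains"))
  sim_loop(cfg, T, noise = noise, schedule = schedule,
           controller = list(type = "pid", gains = unclass(g), ctrl = ctrl),
           ref = ref, keep_states = keep_states,
           theta_A_noise = theta_A_noise)
}
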