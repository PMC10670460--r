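# Core stepping engine shared by the open-loop, PID and RBF-adaptive runs.
#
# All public simulation entry points funnel into sim_loop(), so that a
# controller with zero gains (or zero adaptation rates) reproduces the
# simpler run bit-for-bit under the same noise realisation.
#
# Discretization of the loop: the PID error history, the RBF training and
# the gain adaptation are sampled once per step dt, but the control input
# is re-evaluated at every Runge-Kutta substep from the instantaneous
# error (with the sampled history frozen), i.e. the control law is part of
# the vector field being integrated. A zero-order hold of u over the whole
# step would put the operating gain magnitudes far outside the discrete
# stability region; the substep-refreshed realisation keeps the loop's
# continuous-time phase margins. When the reference is supplied as a model
# configuration, it is integrated jointly with the plant (sharing the noise
# sequence), so the substep error is exact; a plain numeric reference is
# linearly interpolated across the step.

# Draw the per-step noise matrix (n rows, N columns) for a model config.
nm_noise_matrix <- function(cfg, n, seed = cfg$noise$seed) {
  with_seed(seed,
            matrix(stats::rnorm(n * cfg$N, cfg$noise$mean, cfg$noise$sd),
                   n, cfg$N))
}

# Apply a theta_A schedule to a config: returns list of per-segment
# population lists plus the segment index of every sample.
resolve_schedule <- function(cfg, schedule, tvec) {
  if (is.null(schedule)) {
    return(list(pops = list(cfg$populations), seg = rep(1L, length(tvec))))
  }
  stopifnot(is.data.frame(schedule), all(c("time", "theta_A") %in% names(schedule)),
            !is.unsorted(schedule$time))
  if (schedule$time[1L] > 0) {
    schedule <- rbind(data.frame(time = 0, theta_A = cfg$populations[[1L]]$theta_A),
                      schedule)
  }
  pops <- lapply(schedule$theta_A, function(th) {
    lapply(cfg$populations, function(p) {
      p$theta_A <- th
      p
    })
  })
  seg <- findInterval(tvec, schedule$time, left.open = FALSE)
  seg[seg < 1L] <- 1L
  list(pops = pops, seg = seg)
}

# window id per sample (0 = control off); windows is a k x 2 matrix of times
window_ids <- function(tvec, windows) {
  id <- integer(length(tvec))
  if (is.null(windows) || nrow(windows) == 0L) return(id)
  for (w in seq_len(nrow(windows))) {
    id[tvec >= windows[w, 1L] & tvec < windows[w, 2L]] <- w
  }
  id
}

# The engine. controller: NULL or list(type = "pid" | "rbf", gains, ctrl,
# rbf_cfg, rbf_net). ref: numeric vector (length >= n) or an nm_model
# configuration for joint integration. noise: optional pre-drawn matrix
# (shared between plant and reference).
sim_loop <- function(cfg, T, noise = NULL, schedule = NULL, controller = NULL,
                     ref = NULL, keep_states = TRUE, theta_A_noise = NULL) {
  stopifnot(inherits(cfg, "nm_model"), T > 0)
  dt <- cfg$dt
  N <- cfg$N
  n <- floor(T / dt) + 1L
  tvec <- (seq_len(n) - 1L) * dt

  ref_is_model <- inherits(ref, "nm_model")
  if (ref_is_model) {
    stopifnot(ref$N >= 1, abs(ref$dt - dt) < 1e-12)
    if (is.null(noise)) noise <- nm_noise_matrix(ref, n)
    stopifnot(ncol(noise) >= max(N, ref$N))
  } else if (is.null(noise)) {
    noise <- nm_noise_matrix(cfg, n)
  }
  stopifnot(nrow(noise) >= n, ncol(noise) >= N)

  sch <- resolve_schedule(cfg, schedule, tvec)
  dclist <- lapply(sch$pops, dyn_consts, theta_A_noise = theta_A_noise)
  seg <- sch$seg
  K <- cfg$K

  has_ctrl <- !is.null(controller)
  ctype <- if (has_ctrl) controller$type else "none"
  if (has_ctrl) {
    stopifnot(ref_is_model || length(ref) >= n)
    ctrl <- controller$ctrl
    fb <- ctrl$feedback_population
    fpop <- ctrl$F_map[seq(4L, by = 8L, length.out = N)]
    u_limit <- ctrl$u_limit
    n_sub <- if (is.null(ctrl$n_sub)) 2L else as.integer(ctrl$n_sub)
    seed_hist <- isTRUE(ctrl$seed_history)
    wid <- window_ids(tvec, ctrl$windows)
    Kp <- controller$gains[1L]; Ki <- controller$gains[2L]; Kd <- controller$gains[3L]
  } else {
    fpop <- numeric(N)
    wid <- integer(n)
  }

  is_rbf <- identical(ctype, "rbf")
  if (is_rbf) {
    rcfg <- controller$rbf_cfg
    net <- controller$rbf_net
    centers <- net$centers; widths <- net$widths; weights <- net$weights
    centers_p <- centers; widths_p <- widths; weights_p <- weights
    eta <- rcfg$eta; alpha <- rcfg$alpha
    eta_p <- rcfg$eta_p; eta_i <- rcfg$eta_i; eta_d <- rcfg$eta_d
    sscale <- rcfg$state_scale
    wfloor <- rcfg$width_floor
    gfrac <- rcfg$gain_step_frac
    always_train <- isTRUE(rcfg$always_train)
    ucomp <- if (is.null(rcfg$u_compress)) 1 else rcfg$u_compress
    u_max <- 1
    gains_tr <- matrix(NA_real_, n, 3L)
    yhat_tr <- rep(NA_real_, n)
    J2_tr <- rep(NA_real_, n)
  }

  X <- matrix(cfg$x0, 8L, N)
  if (ref_is_model) {
    Xr <- matrix(ref$x0, 8L, ref$N)
    dcr <- dyn_consts(ref$populations)
    Kr <- ref$K
    zr <- numeric(ref$N)
    ref_seq <- numeric(n)
  } else {
    ref_seq <- if (is.null(ref)) NULL else ref[seq_len(n)]
  }
  y <- matrix(0, n, N)
  uvec <- numeric(n)
  xs <- if (keep_states) matrix(0, n, 8L * N) else NULL

  u_base <- 0; e1 <- 0; e2 <- 0
  prev_wid <- 0L

  for (i in seq_len(n)) {
    yi <- X[3L, ] - X[5L, ]
    y[i, ] <- yi
    if (keep_states) xs[i, ] <- X
    if (ref_is_model) {
      r_i <- Xr[3L, 1L] - Xr[5L, 1L]
      ref_seq[i] <- r_i
    } else if (!is.null(ref_seq)) {
      r_i <- ref_seq[i]
    }

    w_i <- wid[i]
    ctrl_on <- has_ctrl && w_i > 0L
    if (ctrl_on) {
      e <- r_i - yi[fb]
      if (w_i != prev_wid) {         # control onset: fresh PID state
        u_base <- 0
        if (seed_hist) {             # backward-extrapolated error history
          e1 <- e; e2 <- e
        } else {
          e1 <- 0; e2 <- 0
        }
      }
      if (!is.finite(e)) {
        stop(sprintf("non-finite control error at t = %.4f s (step %d)",
                     tvec[i], i), call. = FALSE)
      }
      u_i <- u_base + Kp * (e - e1) + Ki * e + Kd * (e - 2 * e1 + e2)
      if (!is.null(u_limit)) u_i <- max(min(u_i, u_limit), -u_limit)

      if (is_rbf) {
        # running normalisation of the control coordinate
        u_max <- max(u_max, abs(u_i))
        xr <- c(X[, 1L] * sscale, u_i / (ucomp * u_max))
        fw <- rbf_forward_raw(centers, widths, weights, xr)
        yhat <- fw$y
        err_est <- yi[fb] - yhat
        jac <- rbf_jacobian_raw(centers, widths, weights, xr, fw$xi) / (ucomp * u_max)

        # online PID gain adaptation from the estimator Jacobian
        dKp <- -eta_p * err_est * jac * (e - e1)
        dKi <- -eta_i * err_est * jac * e
        dKd <- -eta_d * err_est * jac * (e - 2 * e1 + e2)
        if (!is.null(gfrac)) {
          cap <- gfrac * abs(c(Kp, Ki, Kd))
          dKp <- max(min(dKp, cap[1L]), -cap[1L])
          dKi <- max(min(dKi, cap[2L]), -cap[2L])
          dKd <- max(min(dKd, cap[3L]), -cap[3L])
        }
        Kp <- Kp + dKp; Ki <- Ki + dKi; Kd <- Kd + dKd

        # gradient-descent training with momentum on weights/centers/widths
        up <- rbf_update_raw(centers, widths, weights, xr, fw$xi, err_est, eta)
        new_w <- weights + up$dw + alpha * (weights - weights_p)
        new_th <- widths + up$dth + alpha * (widths - widths_p)
        new_c <- centers + up$dc + alpha * (centers - centers_p)
        if (all(is.finite(new_w)) && all(is.finite(new_th)) &&
            all(is.finite(new_c))) {
          weights_p <- weights; weights <- new_w
          widths_p <- widths; widths <- pmax(new_th, wfloor)
          centers_p <- centers; centers <- new_c
        }
        gains_tr[i, ] <- c(Kp, Ki, Kd)
        yhat_tr[i] <- yhat
        J2_tr[i] <- 0.5 * err_est^2
      }
    } else {
      u_i <- 0
      if (is_rbf && always_train) {
        # estimator keeps learning the free-running plant (u = 0 input)
        u_max <- max(u_max, abs(u_i))
        xr <- c(X[, 1L] * sscale, u_i / (ucomp * u_max))
        fw <- rbf_forward_raw(centers, widths, weights, xr)
        err_est <- yi[fb] - fw$y
        up <- rbf_update_raw(centers, widths, weights, xr, fw$xi, err_est, eta)
        new_w <- weights + up$dw + alpha * (weights - weights_p)
        new_th <- widths + up$dth + alpha * (widths - widths_p)
        new_c <- centers + up$dc + alpha * (centers - centers_p)
        if (all(is.finite(new_w)) && all(is.finite(new_th)) &&
            all(is.finite(new_c))) {
          weights_p <- weights; weights <- new_w
          widths_p <- widths; widths <- pmax(new_th, wfloor)
          centers_p <- centers; centers <- new_c
        }
        yhat_tr[i] <- fw$y
        J2_tr[i] <- 0.5 * err_est^2
      }
    }
    prev_wid <- w_i
    uvec[i] <- u_i

    if (i < n) {
      dc <- dclist[[seg[i]]]
      pn <- noise[i, seq_len(N)]
      if (ref_is_model) pnr <- noise[i, seq_len(ref$N)]

      # substep control law: frozen history (u_base, e1, e2), instantaneous e
      if (ctrl_on) {
        r_next <- if (ref_is_model) NA_real_ else
          (if (i + 1L <= length(ref_seq)) ref_seq[i + 1L] else ref_seq[i])
        sub_u <- function(Xs, Xrs, th) {
          r_s <- if (ref_is_model) Xrs[3L, 1L] - Xrs[5L, 1L] else
            (1 - th) * r_i + th * r_next
          e_s <- r_s - (Xs[3L, fb] - Xs[5L, fb])
          us <- u_base + Kp * (e_s - e1) + Ki * e_s + Kd * (e_s - 2 * e1 + e2)
          if (!is.null(u_limit)) us <- max(min(us, u_limit), -u_limit)
          us
        }
      }

      if (ctrl_on) {
        # controlled step: integrate in n_sub internal RK4 substeps so the
        # fast closed-loop crossover modes stay inside the RK4 stability
        # region; the control law is re-evaluated at every stage
        h <- dt / n_sub
        for (ss in seq_len(n_sub)) {
          th0 <- (ss - 1L) / n_sub
          if (ref_is_model) {
            k1  <- deriv_fast(X, pn, sub_u(X, Xr, th0), dc, K, fpop)
            k1r <- deriv_fast(Xr, pnr, 0, dcr, Kr, zr)
            X2 <- X + (h / 2) * k1; Xr2 <- Xr + (h / 2) * k1r
            k2  <- deriv_fast(X2, pn, sub_u(X2, Xr2, th0 + 0.5 / n_sub), dc, K, fpop)
            k2r <- deriv_fast(Xr2, pnr, 0, dcr, Kr, zr)
            X3 <- X + (h / 2) * k2; Xr3 <- Xr + (h / 2) * k2r
            k3  <- deriv_fast(X3, pn, sub_u(X3, Xr3, th0 + 0.5 / n_sub), dc, K, fpop)
            k3r <- deriv_fast(Xr3, pnr, 0, dcr, Kr, zr)
            X4 <- X + h * k3; Xr4 <- Xr + h * k3r
            k4  <- deriv_fast(X4, pn, sub_u(X4, Xr4, th0 + 1 / n_sub), dc, K, fpop)
            k4r <- deriv_fast(Xr4, pnr, 0, dcr, Kr, zr)
            X  <- X + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
            Xr <- Xr + (h / 6) * (k1r + 2 * k2r + 2 * k3r + k4r)
          } else {
            k1 <- deriv_fast(X, pn, sub_u(X, NULL, th0), dc, K, fpop)
            X2 <- X + (h / 2) * k1
            k2 <- deriv_fast(X2, pn, sub_u(X2, NULL, th0 + 0.5 / n_sub), dc, K, fpop)
            X3 <- X + (h / 2) * k2
            k3 <- deriv_fast(X3, pn, sub_u(X3, NULL, th0 + 0.5 / n_sub), dc, K, fpop)
            X4 <- X + h * k3
            k4 <- deriv_fast(X4, pn, sub_u(X4, NULL, th0 + 1 / n_sub), dc, K, fpop)
            X <- X + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
          }
          if (!all(is.finite(X))) break
        }
        if (ref_is_model && !all(is.finite(Xr))) {
          stop(sprintf("reference model diverged at t = %.4f s (step %d)",
                       tvec[i + 1L], i + 1L), call. = FALSE)
        }
      } else {
        if (ref_is_model) {
          k1  <- deriv_fast(X, pn, 0, dc, K, fpop)
          k1r <- deriv_fast(Xr, pnr, 0, dcr, Kr, zr)
          k2  <- deriv_fast(X + (dt / 2) * k1, pn, 0, dc, K, fpop)
          k2r <- deriv_fast(Xr + (dt / 2) * k1r, pnr, 0, dcr, Kr, zr)
          k3  <- deriv_fast(X + (dt / 2) * k2, pn, 0, dc, K, fpop)
          k3r <- deriv_fast(Xr + (dt / 2) * k2r, pnr, 0, dcr, Kr, zr)
          k4  <- deriv_fast(X + dt * k3, pn, 0, dc, K, fpop)
          k4r <- deriv_fast(Xr + dt * k3r, pnr, 0, dcr, Kr, zr)
          X  <- X + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
          Xr <- Xr + (dt / 6) * (k1r + 2 * k2r + 2 * k3r + k4r)
          if (!all(is.finite(Xr))) {
            stop(sprintf("reference model diverged at t = %.4f s (step %d)",
                         tvec[i + 1L], i + 1L), call. = FALSE)
          }
        } else {
          k1 <- deriv_fast(X, pn, 0, dc, K, fpop)
          k2 <- deriv_fast(X + (dt / 2) * k1, pn, 0, dc, K, fpop)
          k3 <- deriv_fast(X + (dt / 2) * k2, pn, 0, dc, K, fpop)
          k4 <- deriv_fast(X + dt * k3, pn, 0, dc, K, fpop)
          X <- X + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
        }
      }

      if (!all(is.finite(X))) {
        stop(sprintf("simulation diverged at t = %.4f s (step %d)",
                     tvec[i + 1L], i + 1L), call. = FALSE)
      }

      if (ctrl_on) {
        e2 <- e1; e1 <- e
        u_base <- u_i
      }
    }
  }

  out <- list(t = tvec, y = y, x = xs,
              p = noise[seq_len(n), seq_len(N), drop = FALSE],
              u = uvec, ref = ref_seq,
              dt = dt, N = N, controller = ctype)
  if (is_rbf) {
    out$gains <- gains_tr
    out$yhat <- yhat_tr
    out$J2 <- J2_tr
    out$rbf_net <- list(centers = centers, widths = widths, weights = weights)
  }
  structure(out, class = "nm_trace")
}

#' Simulate the coupled model without control
#'
#' Integrates the coupled neural mass model with classical fourth-order
#' Runge-Kutta at the configured step, drawing one Gaussian noise sample per
#' population per step (held constant across substeps). With the standard
#' parameters the first population's output is a low-amplitude fluctuation
#' around the alpha-regime operating point; raising the excitatory gains to
#' about 3.5 mV produces continuous high-amplitude spiking.
#'
#' @param cfg A \code{\link{coupled_model_config}}.
#' @param T Duration (s).
#' @param noise Optional pre-drawn noise matrix (\code{floor(T/dt)+1} rows,
#'   N columns); defaults to a fresh draw from \code{cfg$noise}.
#' @param schedule Optional excitatory-gain schedule: a data frame with
#'   columns \code{time} (s) and \code{theta_A} (mV); the gain of every
#'   population switches instantaneously at each breakpoint.
#' @param keep_states Keep the full 8N state trajectory in the trace.
#' @param theta_A_noise Optional fixed excitatory gain (mV) for the
#'   afferent-noise channel, decoupling it from the (possibly scheduled)
#'   sigmoid-channel gain; default uses each population's own theta_A.
#' @return An object of class \code{"nm_trace"}.
#' @export
simulate_open_loop <- function(cfg, T, noise = NULL, schedule = NULL,
                               keep_states = TRUE, theta_A_noise = NULL) {
  sim_loop(cfg, T, noise = noise, schedule = schedule,
           keep_states = keep_states, theta_A_noise = theta_A_noise)
}

#' Reference (expected-output) trajectory
#'
#' Runs the normal-regime model (standard alpha parameters, or the delta
#' parameter set) and returns the first population's output as the reference
#' r(k) for closed-loop control. When \code{noise} is supplied, the reference
#' shares the controlled plant's noise realisation, which makes the reference
#' exactly reachable; pass an independently drawn matrix (or none) for
#' robustness studies.
#'
#' @param cfg_ref A \code{\link{coupled_model_config}} with normal-regime
#'   parameters.
#' @param T Duration (s).
#' @param noise Optional shared noise matrix.
#' @return A list with \code{ref} (the reference sequence, population-1
#'   output) and \code{trace} (the full reference run).
#' @export
reference_trajectory <- function(cfg_ref, T, noise = NULL) {
  tr <- sim_loop(cfg_ref, T, noise = noise, keep_states = FALSE)
  list(ref = tr$y[, 1L], trace = tr)
}
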