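# numeric gradient helper
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

random_net <- function(seed, H = 3, M = 9) {
  cfg <- rbf_config(H = H, M = M, eta = 0.1, alpha = 0)
  net <- rbf_network(cfg, seed = seed)
  set.seed(seed + 500)
  net$weights <- rnorm(H)
  net$widths <- runif(H, 0.5, 2)
  net
}

test_that("rbf forward pass matches closed-form values", {
  cfg <- rbf_config(H = 1, M = 3, eta = 0.1)
  net <- rbf_network(cfg, seed = 1)
  net$weights <- 2
  net$widths <- 1
  net$centers <- matrix(c(0.5, -0.2, 0.1), 1, 3)
  # input at the center: activation exactly 1
  at_c <- rbf_forward(net, as.vector(net$centers))
  expect_equal(at_c$xi, 1)
  expect_equal(at_c$y, 2)
  # squared distance 2 with unit width: y = 2 exp(-1)
  xr <- as.vector(net$centers) + c(1, 1, 0)
  expect_equal(rbf_forward(net, xr)$y, 2 * exp(-1))
  # zero weights estimate zero everywhere
  net$weights <- 0
  expect_equal(rbf_forward(net, c(9, -9, 4))$y, 0)
  expect_error(rbf_forward(net, c(NaN, 0, 0)), "non-finite")
})

test_that("training gradients match central finite differences (50 instances)", {
  for (s in 1:50) {
    net <- random_net(s)
    set.seed(s)
    xr <- runif(9, -1, 1)
    y_true <- rnorm(1)
    J2 <- function(w, th, ctr) {
      d2 <- colSums((t(ctr) - xr)^2)
      xi <- exp(-d2 / (2 * th^2))
      0.5 * (y_true - sum(w * xi))^2
    }
    up <- neuromass:::rbf_update_raw(net$centers, net$widths, net$weights, xr,
                                     rbf_forward(net, xr)$xi,
                                     y_true - rbf_forward(net, xr)$y,
                                     eta = 1)
    gw <- fd_grad(function(w) J2(w, net$widths, net$centers), net$weights)
    gt <- fd_grad(function(th) J2(net$weights, th, net$centers), net$widths)
    gc <- fd_grad(function(cv) J2(net$weights, net$widths,
                                  matrix(cv, nrow(net$centers))),
                  as.vector(net$centers))
    # updates are -eta * gradient (eta = 1 here)
    expect_equal(up$dw, -gw, tolerance = 1e-6)
    expect_equal(up$dth, -gt, tolerance = 1e-6)
    expect_equal(as.vector(up$dc), -gc, tolerance = 1e-6)
  }
})

test_that("the control-input Jacobian matches finite differences and sign logic", {
  for (s in 1:50) {
    net <- random_net(s + 100)
    set.seed(s + 100)
    xr <- runif(9, -1, 1)
    jac <- rbf_jacobian(net, xr)
    fd <- fd_grad(function(u) rbf_forward(net, c(xr[1:8], u))$y, xr[9])
    expect_equal(jac, fd, tolerance = 1e-6)
  }
  # u exactly at every center's u-coordinate: derivative vanishes
  net <- random_net(7)
  net$centers[, 9] <- 0.3
  expect_equal(rbf_jacobian(net, c(runif(8), 0.3)), 0)
  # single positive-weight node with u above its center: negative slope
  cfg <- rbf_config(H = 1, M = 2, eta = 0.1)
  net1 <- rbf_network(cfg, seed = 2)
  net1$weights <- 1.5
  net1$centers <- matrix(c(0, 0), 1, 2)
  expect_lt(rbf_jacobian(net1, c(0, 0.4)), 0)
  # chain rule through the input scaling
  expect_equal(rbf_jacobian(net1, c(0, 0.4), u_scale = 0.25),
               0.25 * rbf_jacobian(net1, c(0, 0.4)))
})

test_that("training descends on a fixed sample and keeps widths positive", {
  cfg <- rbf_config(H = 4, M = 5, eta = 0.05, alpha = 0)
  net <- rbf_network(cfg, seed = 3)
  xr <- c(0.2, -0.4, 0.6, 0, 0.3)
  y_true <- 1.7
  errs <- numeric(100)
  for (k in 1:100) {
    r <- rbf_train_step(net, xr, y_true)
    net <- r$net
    errs[k] <- abs(r$err)
    expect_true(all(net$widths > 0))
  }
  expect_true(all(diff(errs) < 1e-12))
  expect_lt(errs[100], 0.01 * abs(y_true))
  # zero error leaves a momentum-free net unchanged
  net$prev <- NULL
  net2 <- rbf_train_step(net, xr, rbf_forward(net, xr)$y)$net
  expect_equal(net2$weights, net$weights)
  expect_equal(net2$centers, net$centers)
  expect_equal(net2$widths, net$widths)
})

test_that("gain adaptation follows the gradient rule with capping", {
  cfg <- rbf_config(eta_p = 1, eta_i = 1, eta_d = 1, gain_step_frac = NULL)
  g <- pid_gains(100, 50, 10)
  # est_err = 0 or jac = 0: gains unchanged
  expect_equal(unclass(adapt_pid_gains(g, jac = -2, est_err = 0,
                                       errs = c(1, 1, 1), cfg)), unclass(g))
  expect_equal(unclass(adapt_pid_gains(g, jac = 0, est_err = 0.5,
                                       errs = c(1, 1, 1), cfg)), unclass(g))
  # hand-evaluated update: dKp = -1 * 0.5 * (-2) * 0.1 = 0.1
  g2 <- adapt_pid_gains(g, jac = -2, est_err = 0.5, errs = c(0.3, 0.1, 0.05), cfg)
  expect_equal(g2[["Kp"]] - 100, 0.1)
  expect_equal(g2[["Ki"]] - 50, -1 * 0.5 * (-2) * 0.3)
  expect_equal(g2[["Kd"]] - 10, -1 * 0.5 * (-2) * 0.05)
  # the per-step cap binds symmetrically
  cfg2 <- rbf_config(eta_p = 1e6, eta_i = 1e6, eta_d = 1e6,
                     gain_step_frac = 0.01)
  g3 <- adapt_pid_gains(g, jac = -2, est_err = 0.5, errs = c(1, 1, 1), cfg2)
  expect_equal(unclass(g3), unclass(g) * 1.01, ignore_attr = TRUE)
})

test_that("zero adaptation rates reduce the adaptive loop to the fixed-gain loop", {
  cfg_ref <- study_cfg()
  cfg <- study_cfg(theta_A = 3.5)
  n <- 2001
  noise <- neuromass:::nm_noise_matrix(cfg_ref, n)
  ctrl <- control_config(N = 3, windows = c(0, 3))
  g0 <- ga_pid_printed_gains()
  fixed <- run_closed_loop(cfg, ctrl, g0, cfg_ref, 2, noise = noise,
                           keep_states = FALSE, theta_A_noise = 3.25)
  rc <- rbf_config(eta = 0, eta_p = 0, eta_i = 0, eta_d = 0)
  adap <- run_ga_rbf_pid(cfg, ctrl, g0, rc, cfg_ref, 2, noise = noise,
                         rbf_seed = 9, keep_states = FALSE,
                         theta_A_noise = 3.25)
  expect_identical(adap$y, fixed$y)
  expect_identical(adap$u, fixed$u)
})

test_that("the online estimator converges on the fixed-gain run", {
  cfg_ref <- study_cfg()
  cfg <- study_cfg(theta_A = 3.5)
  ctrl <- control_config(N = 3, windows = c(0, 7))
  tr <- run_ga_rbf_pid(cfg, ctrl, ga_rbf_pid_printed_gains(), rbf_config(),
                       cfg_ref, 6, rbf_seed = 1, keep_states = FALSE,
                       theta_A_noise = 3.25)
  inw <- which(!is.na(tr$J2))
  n10 <- length(inw) %/% 10
  expect_lt(median(tr$J2[tail(inw, n10)]), median(tr$J2[head(inw, n10)]))
  est_err <- abs(tr$y[, 1] - tr$yhat)
  p2p <- diff(range(tr$ref))
  expect_lt(est_err[tail(inw, 1)], 0.05 * p2p)
})
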