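# Small model constructors shared across test files. N <= 2 configurations
# trigger the intended "coupled model is meant for N > 2" warning, so the
# helpers wrap them quietly.

quiet_cfg <- function(...) suppressWarnings(coupled_model_config(...))

# single standard population, deterministic drive
single_pop_cfg <- function(mean = 101, sd = 0, seed = 1, dt = 0.001, ...) {
  quiet_cfg(N = 1, K = 0, noise = noise_spec(mean, sd, seed), dt = dt, ...)
}

# the three-population layout used throughout the experiments
study_cfg <- function(theta_A = 3.25, noise = noise_spec(101, 35, 1), ...) {
  quiet_cfg(N = 3, populations = population_params(theta_A = theta_A),
            K = 28, noise = noise, ...)
}

# matrix-form derivative oracle: evaluates the per-population state-space
# form directly from assemble_matrices(), independent of deriv_fast()
matrix_derivative <- function(x, p_noise, u, cfg, F_map = default_F(cfg$N)) {
  N <- cfg$N
  out <- numeric(8 * N)
  X <- matrix(x, 8, N)
  for (l in seq_len(N)) {
    m <- assemble_matrices(cfg$populations[[l]])
    sp <- cfg$populations[[l]]$sigmoid
    coup <- 0
    for (mm in seq_len(N)) {
      if (mm != l) coup <- coup + cfg$K[mm, l] * X[7, mm]
    }
    out[(8 * l - 7):(8 * l)] <-
      m$A %*% X[, l] + m$B %*% sigmoid(as.vector(m$H %*% X[, l]), sp) +
      m$B1 * p_noise[l] + m$D * coup
  }
  out + F_map * u
}
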