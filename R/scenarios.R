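#' Experiment scenario
#'
#' Bundles everything needed to reproduce one closed-loop modulation
#' experiment: the oscillation regime (which fixes the reference model and
#' the noise statistics), the excitatory-gain schedule of the hyperexcited
#' plant, the control windows, the controller and its (initial) gains.
#'
#' The plant and the reference model are driven by the same noise
#' realisation (the reference is exactly reachable), and the gain mutation
#' acts on the synaptic feedback channels while the afferent-noise channel
#' keeps the normal-regime gain; set \code{share_noise = FALSE} or
#' \code{mutate_noise_channel = TRUE} to study the rougher variants.
#'
#' @param name Scenario label.
#' @param regime \code{"alpha"} or \code{"delta"}.
#' @param gain_schedule Data frame with columns \code{time} (s) and
#'   \code{theta_A} (mV); a single row means a fixed gain from t = 0.
#' @param control_windows k x 2 matrix (or length-2 vector) of control
#'   windows (s).
#' @param T Duration (s).
#' @param controller \code{"ga_pid"}, \code{"ga_rbf_pid"} or \code{"none"}.
#' @param gains (Initial) PID gains; defaults to the GA-selected set for the
#'   chosen controller.
#' @param K Coupling strength (uniform all-to-all).
#' @param N Number of populations.
#' @param seed Noise seed.
#' @param rbf A \code{\link{rbf_config}} for the adaptive controller.
#' @param band_frac Steady-band fraction used in the metrics.
#' @param share_noise Drive plant and reference with the same realisation.
#' @param mutate_noise_channel Let the gain schedule also scale the
#'   afferent-noise channel (default FALSE, see above).
#' @param n_sub Internal integration substeps of the controlled plant.
#' @return An object of class \code{"nm_scenario"}.
#' @seealso \code{\link{scenario_preset}} for the named presets.
#' @export
scenario <- function(name, regime = c("alpha", "delta"), gain_schedule,
                     control_windows, T, controller = c("ga_pid", "ga_rbf_pid", "none"),
                     gains = NULL, K = 28, N = 3, seed = 1L,
                     rbf = rbf_config(), band_frac = 0.02,
                     share_noise = TRUE, mutate_noise_channel = FALSE,
                     n_sub = 2L) {
  regime <- match.arg(regime)
  controller <- match.arg(controller)
  stopifnot(is.data.frame(gain_schedule),
            all(c("time", "theta_A") %in% names(gain_schedule)),
            !is.unsorted(gain_schedule$time),
            all(gain_schedule$time >= 0), all(gain_schedule$time <= T))
  if (is.null(gains)) {
    gains <- if (controller == "ga_rbf_pid") ga_rbf_pid_printed_gains()
             else ga_pid_printed_gains()
  }
  structure(list(name = name, regime = regime, gain_schedule = gain_schedule,
                 control_windows = control_windows, T = T,
                 controller = controller, gains = gains, K = K, N = N,
                 seed = as.integer(seed), rbf = rbf, band_frac = band_frac,
                 share_noise = share_noise,
                 mutate_noise_channel = mutate_noise_channel,
                 n_sub = as.integer(n_sub)),
            class = "nm_scenario")
}

#' Named scenario presets
#'
#' The three experiment layouts:
#' \describe{
#'   \item{\code{alpha_fixed}}{20 s, all excitatory gains fixed at 3.5 mV
#'     (continuous spiking without control), alpha-regime reference, control
#'     applied throughout.}
#'   \item{\code{alpha_mutated}}{10 s, gains 3.25 mV mutating to 3.5 mV at
#'     2 s and back at 8 s; control during 4-6 s and 7-10 s.}
#'   \item{\code{delta_mutated}}{10 s, delta parameter set (noise mean 220,
#'     sd 22), gains 2 mV mutating to 3.5 mV at 2 s and back at 8 s; control
#'     during 4-6 s and 7-10 s.}
#' }
#'
#' @param name One of \code{"alpha_fixed"}, \code{"alpha_mutated"},
#'   \code{"delta_mutated"}.
#' @param controller \code{"ga_pid"}, \code{"ga_rbf_pid"} or \code{"none"}.
#' @param seed Noise seed.
#' @param ... Further arguments passed to \code{\link{scenario}}.
#' @return An \code{"nm_scenario"}.
#' @export
#' @examples
#' sc <- scenario_preset("alpha_fixed", controller = "ga_pid", seed = 1)
#' \donttest{
#' res <- run_scenario(sc)
#' res$metrics
#' }
scenario_preset <- function(name = c("alpha_fixed", "alpha_mutated", "delta_mutated"),
                            controller = "ga_pid", seed = 1L, ...) {
  name <- match.arg(name)
  switch(name,
    alpha_fixed = scenario(
      name, regime = "alpha",
      gain_schedule = data.frame(time = 0, theta_A = 3.5),
      control_windows = c(0, 20), T = 20, controller = controller,
      seed = seed, ...),
    alpha_mutated = scenario(
      name, regime = "alpha",
      gain_schedule = data.frame(time = c(0, 2, 8), theta_A = c(3.25, 3.5, 3.25)),
      control_windows = rbind(c(4, 6), c(7, 10)), T = 10,
      controller = controller, seed = seed, ...),
    delta_mutated = scenario(
      name, regime = "delta",
      gain_schedule = data.frame(time = c(0, 2, 8), theta_A = c(2, 3.5, 2)),
      control_windows = rbind(c(4, 6), c(7, 10)), T = 10,
      controller = controller, seed = seed, ...)
  )
}

# regime -> (population params of the normal model, noise spec)
regime_base <- function(regime, seed) {
  if (regime == "alpha") {
    list(pop = population_params(), noise = noise_spec(101, 35, seed))
  } else {
    list(pop = delta_population_params(), noise = noise_spec(220, 22, seed))
  }
}

#' Run a scenario end to end
#'
#' Builds the hyperexcited plant and the normal-regime reference model,
#' runs the requested controller (or none) and computes the tracking
#' metrics. The reference model keeps the regime's normal excitatory gain
#' for the whole run; the plant follows the scenario's gain schedule.
#'
#' @param sc An \code{\link{scenario}} or \code{\link{scenario_preset}}.
#' @param keep_states Keep full state trajectories in the trace.
#' @return A list with \code{trace} (an \code{"nm_trace"}), \code{metrics}
#'   (an \code{"nm_metrics"}, NULL for uncontrolled runs) and \code{scenario}.
#' @export
run_scenario <- function(sc, keep_states = FALSE) {
  stopifnot(inherits(sc, "nm_scenario"))
  base <- regime_base(sc$regime, sc$seed)
  ref_cfg <- suppressWarnings(
    coupled_model_config(N = sc$N, populations = base$pop, K = sc$K,
                         noise = base$noise))
  plant_pop <- base$pop
  plant_pop$theta_A <- sc$gain_schedule$theta_A[1L]
  plant_cfg <- suppressWarnings(
    coupled_model_config(N = sc$N, populations = plant_pop, K = sc$K,
                         noise = base$noise))
  schedule <- if (nrow(sc$gain_schedule) > 1L) sc$gain_schedule else NULL
  thA_noise <- if (sc$mutate_noise_channel) NULL else base$pop$theta_A

  n <- floor(sc$T / plant_cfg$dt) + 1L
  noise <- nm_noise_matrix(ref_cfg, n)

  if (sc$controller == "none") {
    tr <- sim_loop(plant_cfg, sc$T, noise = noise, schedule = schedule,
                   ref = ref_cfg, keep_states = keep_states,
                   theta_A_noise = thA_noise)
    return(list(trace = tr, metrics = NULL, scenario = sc))
  }

  if (!sc$share_noise) {
    # independent realisation for the plant; reference keeps the seed draw
    noise_plant <- nm_noise_matrix(plant_cfg, n, seed = sc$seed + 104729L)
    ref <- reference_trajectory(ref_cfg, sc$T, noise = noise)$ref
    ctrl <- control_config(N = sc$N, windows = sc$control_windows,
                           n_sub = sc$n_sub)
    tr <- if (sc$controller == "ga_pid") {
      run_closed_loop(plant_cfg, ctrl, sc$gains, ref, sc$T,
                      noise = noise_plant, schedule = schedule,
                      keep_states = keep_states, theta_A_noise = thA_noise)
    } else {
      run_ga_rbf_pid(plant_cfg, ctrl, sc$gains, sc$rbf, ref, sc$T,
                     noise = noise_plant, schedule = schedule,
                     rbf_seed = sc$seed, keep_states = keep_states,
                     theta_A_noise = thA_noise)
    }
  } else {
    ctrl <- control_config(N = sc$N, windows = sc$control_windows,
                           n_sub = sc$n_sub)
    tr <- if (sc$controller == "ga_pid") {
      run_closed_loop(plant_cfg, ctrl, sc$gains, ref_cfg, sc$T,
                      noise = noise, schedule = schedule,
                      keep_states = keep_states, theta_A_noise = thA_noise)
    } else {
      run_ga_rbf_pid(plant_cfg, ctrl, sc$gains, sc$rbf, ref_cfg, sc$T,
                     noise = noise, schedule = schedule,
                     rbf_seed = sc$seed, keep_states = keep_states,
                     theta_A_noise = thA_noise)
    }
  }
  list(trace = tr,
       metrics = metrics_report(tr, sc$control_windows, sc$band_frac),
       scenario = sc)
}
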