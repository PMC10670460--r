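#' Read a scenario from a YAML config file
#'
#' A light configuration front end for scripted runs. The file holds one
#' mapping with the fields of \code{\link{scenario}} (either a named
#' \code{preset} plus overrides, or a full scenario: \code{regime},
#' \code{gain_schedule} as a list of \code{[time, theta_A]} pairs,
#' \code{control_windows} as a list of \code{[start, end]} pairs, \code{T},
#' \code{controller}, optional \code{gains} as \code{[Kp, Ki, Kd]},
#' \code{K}, \code{N}, \code{seed}).
#'
#' @param path Path to the YAML file.
#' @return An \code{"nm_scenario"}.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".yml")
#' writeLines(c("preset: alpha_mutated", "controller: ga_pid", "seed: 3"), tmp)
#' sc <- read_scenario_yaml(tmp)
read_scenario_yaml <- function(path) {
  cf <- yaml::read_yaml(path)
  if (!is.null(cf$preset)) {
    args <- list(name = cf$preset,
                 controller = cf$controller %||% "ga_pid",
                 seed = cf$seed %||% 1L)
    if (!is.null(cf$gains)) {
      args$gains <- pid_gains(cf$gains[[1]], cf$gains[[2]], cf$gains[[3]])
    }
    for (f in c("K", "N", "band_frac", "share_noise", "mutate_noise_channel",
                "n_sub")) {
      if (!is.null(cf[[f]])) args[[f]] <- cf[[f]]
    }
    return(do.call(scenario_preset, args))
  }
  stopifnot(!is.null(cf$regime), !is.null(cf$gain_schedule),
            !is.null(cf$control_windows), !is.null(cf$T))
  gs <- do.call(rbind, lapply(cf$gain_schedule, unlist))
  cw <- do.call(rbind, lapply(cf$control_windows, unlist))
  args <- list(name = cf$name %||% "custom", regime = cf$regime,
               gain_schedule = data.frame(time = gs[, 1], theta_A = gs[, 2]),
               control_windows = cw, T = cf$T,
               controller = cf$controller %||% "ga_pid",
               seed = cf$seed %||% 1L)
  if (!is.null(cf$gains)) {
    args$gains <- pid_gains(cf$gains[[1]], cf$gains[[2]], cf$gains[[3]])
  }
  for (f in c("K", "N", "band_frac", "share_noise", "mutate_noise_channel",
              "n_sub")) {
    if (!is.null(cf[[f]])) args[[f]] <- cf[[f]]
  }
  do.call(scenario, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metrics report as JSON
#'
#' Versioned schema: \code{schema_version}, \code{rmse_mV},
#' \code{settling_s}, \code{overshoot_mV}, \code{band_mV},
#' \code{band_frac}, \code{windows_s}.
#'
#' @param m An \code{"nm_metrics"} report.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_json <- function(m, path) {
  stopifnot(inherits(m, "nm_metrics"))
  out <- list(schema_version = "1.0",
              rmse_mV = m$rmse,
              settling_s = m$settling,
              overshoot_mV = m$overshoot,
              band_mV = m$band,
              band_frac = m$band_frac,
              windows_s = apply(m$windows, 1, function(w) list(start = w[1], end = w[2])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
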