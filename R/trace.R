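#' @export
print.nm_trace <- function(x, ...) {
  cat(sprintf("Simulation trace: %d populations, %d samples (dt = %g s, %g s)\n",
              x$N, length(x$t), x$dt, max(x$t)))
  cat(sprintf("  controller: %s%s\n", x$controller,
              if (is.null(x$ref)) "" else "; reference attached"))
  cat(sprintf("  y1 range: [%.3f, %.3f] mV", min(x$y[, 1]), max(x$y[, 1])))
  if (any(x$u != 0)) cat(sprintf("; u range: [%.3g, %.3g]", min(x$u), max(x$u)))
  cat("\n")
  invisible(x)
}

#' Convert a simulation trace to a data frame
#'
#' Columns: \code{t}, \code{y1..yN}, then \code{ref} and \code{u} when the
#' run was controlled, and optionally the full state dump \code{x1..x8N}.
#'
#' @param x An \code{"nm_trace"}.
#' @param row.names,optional Passed on conventionally (unused).
#' @param full_state Include all 8N state columns.
#' @param ... Unused.
#' @return A data.frame with one row per sample.
#' @export
as.data.frame.nm_trace <- function(x, row.names = NULL, optional = FALSE,
                                   full_state = FALSE, ...) {
  d <- data.frame(t = x$t)
  for (l in seq_len(x$N)) d[[paste0("y", l)]] <- x$y[, l]
  if (!is.null(x$ref)) d$ref <- x$ref
  d$u <- x$u
  if (full_state && !is.null(x$x)) {
    xs <- as.data.frame(x$x)
    names(xs) <- paste0("x", seq_len(ncol(xs)))
    d <- cbind(d, xs)
  }
  d
}

#' Write a trace to CSV
#'
#' Deterministic column order and header (\code{t, y1..yN, ref, u, ...}),
#' suitable for re-computing all metrics from the file.
#'
#' @param trace An \code{"nm_trace"}.
#' @param path Output file path.
#' @param full_state Include the full state dump.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path, full_state = FALSE) {
  utils::write.csv(as.data.frame(trace, full_state = full_state), path,
                   row.names = FALSE)
  invisible(path)
}

#' Plot a simulation trace
#'
#' Population-1 output against time, with the reference overlaid for
#' controlled runs.
#'
#' @param x An \code{"nm_trace"}.
#' @param population Which population's output to draw.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.nm_trace <- function(x, population = 1L, ...) {
  graphics::plot(x$t, x$y[, population], type = "l", col = "blue",
                 xlab = "time (s)", ylab = sprintf("y%d (mV)", population),
                 ...)
  if (!is.null(x$ref) && population == 1L) {
    graphics::lines(x$t, x$ref, col = "red")
    graphics::legend("topright", legend = c("controlled output", "reference"),
                     col = c("blue", "red"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Dominant frequency of a signal
#'
#' Smoothed-periodogram estimate of the dominant oscillation frequency,
#' optionally restricted to frequencies above a floor (to look past slow
#' noise-driven drift).
#'
#' @param y Signal values at uniform spacing \code{dt}.
#' @param dt Sampling interval (s).
#' @param min_freq Ignore spectral content below this frequency (Hz).
#' @return Frequency (Hz) of the spectral peak.
#' @export
dominant_frequency <- function(y, dt, min_freq = 0.5) {
  sp <- stats::spec.pgram(stats::ts(y, deltat = dt), spans = c(21, 21),
                          taper = 0.1, detrend = TRUE, plot = FALSE)
  ok <- sp$freq >= min_freq
  sp$freq[ok][which.max(sp$spec[ok])]
}
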