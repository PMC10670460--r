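#' Root-mean-square tracking error
#'
#' \eqn{R(y_c) = \sqrt{\frac{1}{n}\sum_k (r(k)-y_c(k))^T(r(k)-y_c(k))}}.
#' Zero if and only if the two sequences are identical; the study's
#' control-accuracy metric.
#'
#' @param ref Reference sequence (vector, or matrix with one column per
#'   output component).
#' @param yc Controlled output sequence, same shape.
#' @return Non-negative scalar (mV for membrane-potential outputs).
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt((9 + 16) / 2)
rmse <- function(ref, yc) {
  ref <- as.matrix(ref); yc <- as.matrix(yc)
  if (!identical(dim(ref), dim(yc))) {
    stop("reference and output must have the same length/shape", call. = FALSE)
  }
  stopifnot(nrow(ref) >= 1)
  sqrt(sum((ref - yc)^2) / nrow(ref))
}

#' Settling (adjustment) time after a control onset
#'
#' The time after \code{onset} at which the absolute tracking error enters
#' the steady band and stays inside it until \code{end}. Returns the window
#' length when the error never settles.
#'
#' @param t Sample times (s).
#' @param err Absolute tracking error |yc - ref| at those times (mV).
#' @param onset Control onset time (s).
#' @param end End of the control window (s).
#' @param band Steady band half-width (mV).
#' @return Settling time in seconds (>= 0).
#' @export
settling_time <- function(t, err, onset, end, band) {
  stopifnot(length(t) == length(err), band >= 0, end > onset)
  sel <- t >= onset & t < end
  if (!any(sel)) stop("onset/end outside the trace", call. = FALSE)
  ts <- t[sel]; es <- abs(err[sel])
  out <- es > band
  if (!any(out)) return(0)
  last_out <- max(which(out))
  if (last_out == length(es)) return(end - onset)   # never settles
  ts[last_out + 1L] - onset
}

#' Peak overshoot beyond the steady band
#'
#' Ringing measure of the onset transient. At a control onset the tracking
#' error necessarily starts outside the steady band (the uncontrolled plant
#' has drifted from the reference), so the initial approach itself is not an
#' overshoot. What distinguishes a well-damped loop from a ringing one is
#' whether the error swings \emph{past} the reference: the overshoot is the
#' largest excursion beyond the steady band on the side opposite to the
#' initial error, during the transient (from \code{onset} until the error
#' settles, or the whole window if it never does). A monotone decay into the
#' band scores zero.
#'
#' @param t Sample times (s).
#' @param err Signed tracking error yc - ref at those times (mV).
#' @param onset Control onset time (s).
#' @param end End of the control window (s).
#' @param band Steady band half-width (mV).
#' @return Overshoot in mV (>= 0).
#' @export
overshoot <- function(t, err, onset, end, band) {
  stopifnot(length(t) == length(err), band >= 0, end > onset)
  st <- settling_time(t, err, onset, end, band)
  sel <- t >= onset & t < onset + max(st, 0) + 1e-12
  if (!any(sel)) return(0)
  es <- err[sel]
  first_out <- which(abs(es) > band)
  if (length(first_out) == 0L) return(0)
  sgn <- sign(es[first_out[1L]])     # direction of the initial approach
  max(0, max(-sgn * es) - band)
}

#' Steady tracking band from the reference amplitude
#'
#' The settling band convention used throughout the package: a fraction
#' (default 2\%) of the reference's peak-to-peak amplitude over the control
#' window.
#'
#' @param ref Reference sequence over the control window.
#' @param frac Band fraction of the peak-to-peak amplitude.
#' @return Band half-width (mV).
#' @export
steady_band <- function(ref, frac = 0.02) {
  stopifnot(frac > 0)
  frac * (max(ref) - min(ref))
}

#' Tracking-performance report for a controlled trace
#'
#' Computes the RMSE over the whole trace and, for each control window, the
#' settling time and the peak overshoot at its onset, using the steady-band
#' convention of \code{\link{steady_band}}.
#'
#' @param trace An \code{"nm_trace"} from a controlled run (must carry
#'   \code{ref}).
#' @param windows Control windows (k x 2 matrix of times, s).
#' @param band_frac Steady-band fraction of the reference peak-to-peak.
#' @return A list of class \code{"nm_metrics"}: \code{rmse} (mV),
#'   \code{settling} and \code{overshoot} (one entry per window),
#'   \code{band} (the band half-widths used, mV).
#' @export
metrics_report <- function(trace, windows, band_frac = 0.02) {
  stopifnot(inherits(trace, "nm_trace"), !is.null(trace$ref))
  if (is.vector(windows) && length(windows) == 2L) {
    windows <- matrix(windows, 1L, 2L)
  }
  err <- trace$y[, 1L] - trace$ref
  n_w <- nrow(windows)
  settling <- numeric(n_w); osh <- numeric(n_w); bands <- numeric(n_w)
  for (w in seq_len(n_w)) {
    onset <- windows[w, 1L]; end <- min(windows[w, 2L], max(trace$t))
    sel <- trace$t >= onset & trace$t < end
    bands[w] <- steady_band(trace$ref[sel], band_frac)
    settling[w] <- settling_time(trace$t, err, onset, end, bands[w])
    osh[w] <- overshoot(trace$t, err, onset, end, bands[w])
  }
  structure(list(rmse = rmse(trace$ref, trace$y[, 1L]),
                 settling = settling, overshoot = osh, band = bands,
                 band_frac = band_frac, windows = windows),
            class = "nm_metrics")
}

#' @export
print.nm_metrics <- function(x, ...) {
  cat(sprintf("Tracking RMSE: %.4e mV\n", x$rmse))
  for (w in seq_along(x$settling)) {
    cat(sprintf("  window %d (onset %g s): settling %.4f s, overshoot %.4e mV (band %.3e mV)\n",
                w, x$windows[w, 1L], x$settling[w], x$overshoot[w], x$band[w]))
  }
  invisible(x)
}
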