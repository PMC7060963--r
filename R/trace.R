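#' Fluorescence trace
#'
#' A uniformly sampled fluorescence time series: either raw mean line
#' intensity (arbitrary units) or F/F0 after normalization.
#'
#' @param value Numeric vector of fluorescence values.
#' @param line_rate_hz Sampling rate in Hz (> 0); the time grid is
#'   `(seq_along(value) - 1) / line_rate_hz`.
#' @param normalized Logical; `TRUE` once the trace has been divided by its
#'   resting baseline F0.
#' @param f0 Baseline used for normalization (present iff `normalized`).
#' @param smoothed Logical; `TRUE` after [smooth_trace()].
#' @return An object of class `fluor_trace` with elements `time_s`,
#'   `value`, `line_rate_hz`, `normalized`, `f0`, `smoothed`.
#' @export
fluor_trace <- function(value, line_rate_hz, normalized = FALSE, f0 = NULL,
                        smoothed = FALSE) {
  stopifnot(is.numeric(value), length(value) >= 1)
  if (line_rate_hz <= 0) stop("line_rate_hz must be > 0")
  if (normalized && is.null(f0)) stop("normalized traces must record f0")
  structure(list(time_s = (seq_along(value) - 1) / line_rate_hz,
                 value = as.numeric(value),
                 line_rate_hz = line_rate_hz,
                 normalized = normalized,
                 f0 = f0,
                 smoothed = smoothed),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: %d samples at %.6g Hz (%.3g s)%s%s\n",
              length(x$value), x$line_rate_hz,
              length(x$value) / x$line_rate_hz,
              if (x$smoothed) ", smoothed" else "",
              if (x$normalized) sprintf(", F/F0 (F0 = %.4g)", x$f0) else ""))
  cat(sprintf("  range %.4g .. %.4g\n", min(x$value), max(x$value)))
  invisible(x)
}

#' @export
plot.fluor_trace <- function(x, ...) {
  plot(x$time_s, x$value, type = "l", xlab = "time (s)",
       ylab = if (x$normalized) "F/F0" else "F (a.u.)", ...)
  invisible(x)
}

#' Extract the mean-intensity trace from a line-scan recording
#'
#' Collapses the spatial (pixel) axis: the trace value at line `t` is the
#' mean over pixels of row `t`, sampled at the line rate.
#'
#' @param rec A [linescan()] recording.
#' @return A raw (unnormalized) [fluor_trace()].
#' @export
extract_trace <- function(rec) {
  stopifnot(inherits(rec, "linescan"))
  fluor_trace(rowMeans(rec$intensity), line_rate_hz = rec$line_rate_hz)
}

#' Savitzky-Golay smoothing of a trace
#'
#' Local least-squares polynomial smoothing: at each sample a polynomial of
#' the given order is fitted over a centered window of `2 * neighbors + 1`
#' points and evaluated at the center (the Savitzky-Golay scheme). At the
#' edges the polynomial fitted to the nearest full window is extrapolated.
#' The default, order 6 with 10 neighbors on either side, reproduces the
#' "6th order, 10 neighbors" smoothing used upstream of transient analysis.
#'
#' Smoothing is linear and preserves polynomials up to the fit order, so a
#' trace that is exactly a degree-6 polynomial passes through unchanged.
#'
#' @param trace A [fluor_trace()].
#' @param order Polynomial order (default 6).
#' @param neighbors Half-window size (default 10; window 21).
#' @return The smoothed [fluor_trace()] on the same time grid.
#' @export
smooth_trace <- function(trace, order = 6, neighbors = 10) {
  stopifnot(inherits(trace, "fluor_trace"))
  window <- 2 * neighbors + 1
  if (order >= window)
    stop("polynomial order must be smaller than the window 2*neighbors + 1")
  if (length(trace$value) < window)
    stop("trace shorter than the smoothing window")
  out <- trace
  out$value <- as.numeric(signal::sgolayfilt(trace$value, p = order, n = window))
  out$smoothed <- TRUE
  out
}

#' Normalize a trace to its resting baseline
#'
#' Divides the trace by the resting fluorescence F0 (typically obtained
#' from [detect_baseline()]), yielding the dimensionless F/F0 convention in
#' which amplitudes are reported.
#'
#' @param trace A [fluor_trace()] that has not been normalized yet.
#' @param f0 Baseline fluorescence (> 0) in trace units.
#' @return The normalized [fluor_trace()] (resting level approximately 1).
#' @export
normalize_f0 <- function(trace, f0) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (trace$normalized) stop("trace is already normalized")
  if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0) stop("f0 must be > 0")
  out <- trace
  out$value <- trace$value / f0
  out$normalized <- TRUE
  out$f0 <- f0
  out
}
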