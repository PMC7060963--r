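.excluded <- function(reason)
  structure(list(reason = reason), class = "excluded_measurement")

#' Test whether a measurement was excluded
#'
#' [measure_transient()] and [summarize_cell()] return an
#' `excluded_measurement` sentinel (carrying the `reason`) instead of
#' metrics when an epoch holds no usable transient or a cell no usable
#' epoch.
#'
#' @param x Any object.
#' @return `TRUE` for an exclusion sentinel.
#' @export
is_excluded <- function(x) inherits(x, "excluded_measurement")

#' @export
print.excluded_measurement <- function(x, ...) {
  cat("Excluded:", x$reason, "\n")
  invisible(x)
}

#' Estimate the resting fluorescence level of a trace
#'
#' Robust automatic resting-level estimate: the median of all samples at or
#' below the 20th percentile of the trace. At 0.25 Hz pacing the transient
#' occupies a small duty cycle, so the lowest fifth of the samples sits on
#' the diastolic baseline and the estimator ignores the transients
#' entirely. For a constant trace it returns that constant.
#'
#' @param trace A [fluor_trace()] with at least 100 samples.
#' @return The baseline level, in trace units.
#' @export
detect_baseline <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  v <- trace$value
  if (length(v) < 100) stop("trace too short for baseline detection (< 100 samples)")
  if (all(v == 0)) stop("flat-zero trace: no dynamic range for a baseline")
  q20 <- stats::quantile(v, 0.2, names = FALSE, type = 7)
  stats::median(v[v <= q20])
}

#' Split a paced trace into stimulation epochs
#'
#' Returns the contiguous windows of length `1 / pacing_hz` anchored at
#' `stim_offset_s`; a trailing partial epoch is dropped.
#'
#' @param trace A [fluor_trace()].
#' @param pacing_hz Stimulation frequency in Hz (> 0, below the line rate).
#' @param stim_offset_s Time of the first stimulus (s, default 0).
#' @return A data frame with one row per epoch: `epoch`, `start_index`,
#'   `end_index`, `start_s`.
#' @examples
#' tr <- fluor_trace(rep(1, 20000), line_rate_hz = 1057.7)
#' nrow(segment_transients(tr, pacing_hz = 0.25))  # 4 full epochs
#' @export
segment_transients <- function(trace, pacing_hz, stim_offset_s = 0) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (pacing_hz <= 0) stop("pacing_hz must be > 0")
  if (pacing_hz >= trace$line_rate_hz)
    stop("pacing faster than the line rate: epochs would hold < 1 sample")
  if (stim_offset_s < 0) stop("stim_offset_s must be >= 0")
  epoch_s <- 1 / pacing_hz
  total_s <- length(trace$value) / trace$line_rate_hz
  n_epochs <- floor((total_s - stim_offset_s) / epoch_s + 1e-9)
  if (n_epochs < 1) stop("trace holds no full pacing epoch")
  starts <- stim_offset_s + (seq_len(n_epochs) - 1) * epoch_s
  start_idx <- floor(starts * trace$line_rate_hz + 1e-9) + 1
  end_idx <- floor((starts + epoch_s) * trace$line_rate_hz + 1e-9)
  end_idx <- pmin(end_idx, length(trace$value))
  data.frame(epoch = seq_len(n_epochs), start_index = start_idx,
             end_index = end_idx, start_s = starts)
}

#' Measure one calcium transient
#'
#' Quantifies a single epoch of a (typically smoothed, F/F0-normalized)
#' trace. The peak is the maximum of the epoch (earliest index on ties) and
#' `height = peak - baseline`. Onset (TStart) is the last upward crossing
#' of `baseline + 0.15 * height` before the peak and decay-50 is the first
#' time after the peak at which the trace falls to `baseline + 0.5 *
#' height`; both crossing times are refined by linear interpolation between
#' samples, removing the quantization of the line period.
#'
#' Epochs with no peak exceeding the baseline by the minimum prominence, or
#' whose trace never reaches half-decay within the epoch, are excluded:
#' the return value is `NULL` with the reason in `attr(, "reason")`.
#'
#' @param trace A [fluor_trace()].
#' @param window One row of [segment_transients()] output (or any list with
#'   `start_index` and `end_index`); `NULL` uses the whole trace.
#' @param baseline Resting level in trace units (1 for a normalized trace);
#'   computed with [detect_baseline()] if missing.
#' @param prominence Minimum height as a fraction of baseline for an epoch
#'   to count as containing a transient (default 0.10).
#' @return A one-row data frame (class `transient_metrics`): `t_start_s`,
#'   `t_peak_s`, `amplitude`, `rise_time_ms`, `decay50_ms`, `baseline` --
#'   or an `excluded_measurement` sentinel (see [is_excluded()]) carrying
#'   the exclusion reason.
#' @export
measure_transient <- function(trace, window = NULL, baseline = NULL,
                              prominence = 0.10) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (is.null(baseline)) baseline <- detect_baseline(trace)
  i0 <- if (is.null(window)) 1L else window$start_index
  i1 <- if (is.null(window)) length(trace$value) else window$end_index
  v <- trace$value[i0:i1]
  dt <- 1 / trace$line_rate_hz
  ip <- which.max(v)                       # earliest index wins on ties
  peak <- v[ip]
  height <- peak - baseline
  if (height < prominence * baseline) return(.excluded("no transient"))
  # onset: last sub- to supra-threshold crossing before the peak
  th_start <- baseline + 0.15 * height
  below <- which(v[seq_len(ip)] < th_start)
  if (length(below) == 0 || max(below) == ip)
    return(.excluded("no onset crossing"))
  j <- max(below)                          # v[j] < th <= v[j + 1]
  fr <- (th_start - v[j]) / (v[j + 1] - v[j])
  t_start <- (j - 1 + fr) * dt
  # decay-50: first descent below baseline + height/2 after the peak
  th_half <- baseline + 0.5 * height
  after <- v[ip:length(v)]
  k <- which(after <= th_half)[1]
  if (is.na(k)) return(.excluded("no half-decay within epoch"))
  k <- ip + k - 1
  fr2 <- (v[k - 1] - th_half) / (v[k - 1] - v[k])
  t_half <- (k - 2 + fr2) * dt
  t_peak <- (ip - 1) * dt
  out <- data.frame(t_start_s = t_start + (i0 - 1) * dt,
                    t_peak_s = t_peak + (i0 - 1) * dt,
                    amplitude = peak,
                    rise_time_ms = (t_peak - t_start) * 1000,
                    decay50_ms = (t_half - t_peak) * 1000,
                    baseline = baseline)
  class(out) <- c("transient_metrics", "data.frame")
  out
}

#' Summarize a cell over its measured transients
#'
#' Unweighted per-metric means over the valid transients of one cell (the
#' recording protocol targets 4 epochs per cell; excluded epochs are simply
#' not counted).
#'
#' @param metrics A list of [measure_transient()] results (excluded epochs
#'   are skipped) or a `transient_metrics` data frame.
#' @param cell_id,batch_id Identifiers carried into the summary.
#' @return A one-row data frame: `cell_id`, `diff_batch`,
#'   `n_transients_used`, `amplitude`, `rise_time_ms`, `decay50_ms` -- or
#'   an `excluded_measurement` sentinel if no transient survived.
#' @export
summarize_cell <- function(metrics, cell_id = "cell", batch_id = NA) {
  if (is.data.frame(metrics)) metrics <- list(metrics)
  metrics <- Filter(is.data.frame, metrics)
  if (length(metrics) == 0) return(.excluded("no valid transients"))
  m <- do.call(rbind, metrics)
  data.frame(cell_id = cell_id, diff_batch = batch_id,
             n_transients_used = nrow(m),
             amplitude = mean(m$amplitude),
             rise_time_ms = mean(m$rise_time_ms),
             decay50_ms = mean(m$decay50_ms))
}

#' Full single-cell analysis chain
#'
#' Runs the canonical pipeline on one recording: extract the mean-intensity
#' trace, Savitzky-Golay smoothing, baseline detection on the smoothed
#' trace, F/F0 normalization, epoch segmentation at the pacing rate, and
#' per-epoch transient measurement, ending in a [summarize_cell()] row.
#'
#' @param rec A [linescan()].
#' @param pacing_hz Stimulation frequency (default taken from the attached
#'   ground truth, else 0.25 Hz).
#' @param stim_offset_s Time of the first stimulus (s).
#' @param order,neighbors Smoothing parameters, see [smooth_trace()].
#' @param prominence See [measure_transient()].
#' @param cell_id,batch_id Identifiers (defaults from recording metadata).
#' @return A list: `summary` (one-row data frame or `NULL`), `metrics`
#'   (per-epoch list), `n_excluded`, `trace` (the smoothed, normalized
#'   [fluor_trace()]), `f0`.
#' @export
analyze_recording <- function(rec, pacing_hz = NULL, stim_offset_s = 0,
                              order = 6, neighbors = 10, prominence = 0.10,
                              cell_id = NULL, batch_id = NULL) {
  stopifnot(inherits(rec, "linescan"))
  if (is.null(pacing_hz))
    pacing_hz <- if (!is.null(rec$truth)) rec$truth$pacing_hz else 0.25
  if (is.null(cell_id))
    cell_id <- if (!is.null(rec$metadata$cell_id)) rec$metadata$cell_id else "cell"
  if (is.null(batch_id))
    batch_id <- if (!is.null(rec$metadata$diff_batch)) rec$metadata$diff_batch else NA
  tr <- smooth_trace(extract_trace(rec), order = order, neighbors = neighbors)
  f0 <- detect_baseline(tr)
  tr <- normalize_f0(tr, f0)
  baseline <- detect_baseline(tr)          # = 1 up to floating point
  windows <- segment_transients(tr, pacing_hz, stim_offset_s)
  metrics <- lapply(seq_len(nrow(windows)), function(i)
    measure_transient(tr, windows[i, ], baseline = baseline,
                      prominence = prominence))
  list(summary = summarize_cell(metrics, cell_id, batch_id),
       metrics = metrics,
       n_excluded = sum(vapply(metrics, is_excluded, logical(1))),
       trace = tr, f0 = f0)
}
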