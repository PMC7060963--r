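#' Transient waveform parameters
#'
#' Ground-truth description of a single paced calcium transient: the peak
#' F/F0 ratio, the onset-to-peak rise time (measured from the 15%-height
#' crossing, the same convention the analyzer uses), the peak-to-half-decay
#' time, the resting fluorescence level and the pacing rate.
#'
#' A transient must fit comfortably inside one pacing epoch:
#' `rise_time_ms + 2 * decay50_ms < 1000 / pacing_hz`.
#'
#' @param amplitude_peak Peak F/F0 ratio (dimensionless, >= 1). A value of
#'   exactly 1 encodes a cell with no transient.
#' @param rise_time_ms Time from the 15%-height onset to the peak (ms, > 0).
#' @param decay50_ms Time from the peak until the signal has lost half of
#'   its height (ms, > 0).
#' @param baseline_f0 Mean resting intensity in arbitrary photon units (> 0).
#' @param pacing_hz Field-stimulation frequency (Hz, > 0).
#' @return An object of class `transient_params`.
#' @examples
#' transient_params(2.8, 169.5, 603.5)
#' @export
transient_params <- function(amplitude_peak, rise_time_ms, decay50_ms,
                             baseline_f0 = 100, pacing_hz = 0.25) {
  stopifnot(is.numeric(amplitude_peak), length(amplitude_peak) == 1L,
            is.numeric(rise_time_ms), is.numeric(decay50_ms),
            is.numeric(baseline_f0), is.numeric(pacing_hz))
  if (amplitude_peak < 1)
    stop("amplitude_peak must be >= 1 (F/F0 ratio)")
  if (rise_time_ms <= 0) stop("rise_time_ms must be > 0")
  if (decay50_ms <= 0) stop("decay50_ms must be > 0")
  if (baseline_f0 <= 0) stop("baseline_f0 must be > 0")
  if (pacing_hz <= 0) stop("pacing_hz must be > 0")
  epoch_ms <- 1000 / pacing_hz
  if (rise_time_ms + 2 * decay50_ms >= epoch_ms)
    stop(sprintf(
      "transient does not fit one pacing epoch: rise_time_ms + 2*decay50_ms = %.1f ms >= %.1f ms",
      rise_time_ms + 2 * decay50_ms, epoch_ms))
  structure(list(amplitude_peak = amplitude_peak,
                 rise_time_ms = rise_time_ms,
                 decay50_ms = decay50_ms,
                 baseline_f0 = baseline_f0,
                 pacing_hz = pacing_hz),
            class = "transient_params")
}

#' @export
print.transient_params <- function(x, ...) {
  cat(sprintf(
    "Transient parameters: amplitude %.3g F/F0, rise %.4g ms, decay50 %.4g ms\n",
    x$amplitude_peak, x$rise_time_ms, x$decay50_ms))
  cat(sprintf("  baseline F0 %.4g a.u., pacing %.3g Hz\n",
              x$baseline_f0, x$pacing_hz))
  invisible(x)
}

#' Line-scan acquisition parameters
#'
#' Describes the confocal line-scan acquisition: spatial samples per line,
#' physical scan width, line rate, number of lines, the intensity-to-photon
#' scale used by the Poisson noise model, and an optional monoexponential
#' photobleaching rate.
#'
#' @param n_pixels Spatial samples per line (>= 8). Default 512.
#' @param scan_width_um Physical scan length in micrometres. Default 45.
#' @param line_rate_hz Lines per second (> 0). Default 1057.7.
#' @param n_lines Number of lines per recording (>= 1). Default 20000.
#' @param photon_gain Expected photons per intensity unit per pixel (> 0).
#'   The default of 0.5 yields about 50 expected photons per pixel at a
#'   resting intensity of 100 a.u.
#' @param bleach_rate Monoexponential photobleaching constant (1/s, >= 0).
#'   Default 0 (no bleaching).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(n_pixels = 512, scan_width_um = 45,
                               line_rate_hz = 1057.7, n_lines = 20000,
                               photon_gain = 0.5, bleach_rate = 0) {
  if (n_pixels < 8) stop("n_pixels must be >= 8")
  if (line_rate_hz <= 0) stop("line_rate_hz must be > 0")
  if (n_lines < 1) stop("n_lines must be >= 1")
  if (photon_gain <= 0) stop("photon_gain must be > 0")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  structure(list(n_pixels = as.integer(n_pixels),
                 scan_width_um = scan_width_um,
                 line_rate_hz = line_rate_hz,
                 n_lines = as.integer(n_lines),
                 photon_gain = photon_gain,
                 bleach_rate = bleach_rate),
            class = "acquisition_params")
}

#' Population preset for a cell group
#'
#' Generative description of a cell population (e.g. wild type or knockout,
#' with or without helothermine): group-level mean transient parameters plus
#' hierarchical variance components. Cells are nested in differentiation
#' batches; each batch contributes an additive Normal shift per metric with
#' standard deviation `sd_between_diff`, and cells scatter around the
#' batch-shifted mean with standard deviation `cv_between_cell * mean`.
#'
#' @param group_label One of `"WT"`, `"KO"`, `"WT_HELHO"`, `"KO_HELHO"`,
#'   or any other label for a custom group.
#' @param mean_params A [transient_params()] object with group-level means.
#' @param cv_between_cell Coefficient of variation across cells, applied to
#'   each metric (scalar or named vector over
#'   `c("amplitude_peak", "rise_time_ms", "decay50_ms")`).
#' @param sd_between_diff Between-differentiation-batch SD per metric, in
#'   the units of the metric (named vector, or a single fraction of the
#'   mean if given as `sd_frac_between_diff`).
#' @param sd_frac_between_diff Convenience alternative: a single fraction of
#'   each metric mean used as the between-batch SD. Default 0.05.
#' @param n_diff Number of differentiation batches (>= 1). Default 3.
#' @param helothermine_conc_uM Treatment concentration (0 or 5 in the
#'   presets). Default 0.
#' @param default_n_cells Number of cells recorded for this group when none
#'   is given explicitly.
#' @return An object of class `population_preset`.
#' @seealso [ca_preset()] for the four calibrated presets.
#' @export
population_preset <- function(group_label, mean_params,
                              cv_between_cell = 0.2,
                              sd_between_diff = NULL,
                              sd_frac_between_diff = 0.05,
                              n_diff = 3,
                              helothermine_conc_uM = 0,
                              default_n_cells = 180) {
  stopifnot(inherits(mean_params, "transient_params"))
  metrics <- c("amplitude_peak", "rise_time_ms", "decay50_ms")
  means <- unlist(mean_params[metrics])
  cv <- if (length(cv_between_cell) == 1L)
    stats::setNames(rep(cv_between_cell, 3), metrics) else cv_between_cell[metrics]
  if (any(cv < 0)) stop("cv_between_cell must be >= 0")
  if (is.null(sd_between_diff))
    sd_between_diff <- sd_frac_between_diff * means
  sd_between_diff <- stats::setNames(as.numeric(sd_between_diff[metrics]), metrics)
  if (any(sd_between_diff < 0)) stop("sd_between_diff must be >= 0")
  if (n_diff < 1) stop("n_diff must be >= 1")
  structure(list(group_label = group_label,
                 mean_params = mean_params,
                 cv_between_cell = cv,
                 sd_between_diff = sd_between_diff,
                 n_diff = as.integer(n_diff),
                 helothermine_conc_uM = helothermine_conc_uM,
                 default_n_cells = as.integer(default_n_cells)),
            class = "population_preset")
}

#' Calibrated cell-group presets
#'
#' The four study conditions: isogenic wild type (WT), CRISPLD1 knockout
#' (KO), and both lines treated with 5 uM helothermine. Group means are
#' calibrated to the reported population means: amplitudes 2.8 / 3.5 /
#' 2.5 / 2.8 F/F0, rise times 169.5 / 199.0 / 207.1 / 170.0 ms and decay-50
#' times 603.5 / 460.8 / 731.9 / 650.2 ms for WT / KO / WT+helothermine /
#' KO+helothermine, recorded at 0.25 Hz pacing. Cell counts default to the
#' reported 181 (WT) and 183 (KO) cells; treated groups default to 180.
#' Between-cell CV is 0.2 and the between-batch SD is 5% of each metric
#' mean over 3 differentiation batches.
#'
#' @param group One of `"WT"`, `"KO"`, `"WT_HELHO"`, `"KO_HELHO"`.
#' @param ... Overrides passed on to [population_preset()].
#' @return A [population_preset()] object.
#' @examples
#' ca_preset("WT")
#' @export
ca_preset <- function(group = c("WT", "KO", "WT_HELHO", "KO_HELHO"), ...) {
  group <- match.arg(group)
  tab <- list(
    WT       = list(amp = 2.8, rise = 169.5, decay = 603.5, helho = 0, n = 181L),
    KO       = list(amp = 3.5, rise = 199.0, decay = 460.8, helho = 0, n = 183L),
    WT_HELHO = list(amp = 2.5, rise = 207.1, decay = 731.9, helho = 5, n = 180L),
    KO_HELHO = list(amp = 2.8, rise = 170.0, decay = 650.2, helho = 5, n = 180L)
  )[[group]]
  args <- list(
    group_label = group,
    mean_params = transient_params(tab$amp, tab$rise, tab$decay),
    helothermine_conc_uM = tab$helho,
    default_n_cells = tab$n
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(population_preset, args)
}

#' @export
print.population_preset <- function(x, ...) {
  cat(sprintf("Population preset '%s' (%d batches, helothermine %g uM)\n",
              x$group_label, x$n_diff, x$helothermine_conc_uM))
  print(x$mean_params)
  cat(sprintf("  between-cell CV %.2g; between-batch SD %s\n",
              x$cv_between_cell[[1]],
              paste(signif(x$sd_between_diff, 3), collapse = "/")))
  invisible(x)
}
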