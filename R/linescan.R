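#' Line-scan recording
#'
#' A 2-D confocal line-scan: rows are successive lines (time), columns are
#' pixels along the scanned line (space).
#'
#' @param intensity Non-negative numeric matrix, lines x pixels.
#' @param line_rate_hz Lines per second (> 0).
#' @param pixel_size_um Pixel size along the line, in micrometres.
#' @param metadata Free-form provenance list.
#' @param truth Optional ground-truth [transient_params()] attached by the
#'   generator.
#' @return An object of class `linescan`.
#' @export
linescan <- function(intensity, line_rate_hz, pixel_size_um = NA_real_,
                     metadata = list(), truth = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a 2-D numeric matrix (lines x pixels)")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (line_rate_hz <= 0) stop("line_rate_hz must be > 0")
  structure(list(intensity = intensity,
                 line_rate_hz = line_rate_hz,
                 pixel_size_um = pixel_size_um,
                 metadata = metadata,
                 truth = truth),
            class = "linescan")
}

#' @export
print.linescan <- function(x, ...) {
  cat(sprintf("Line-scan recording: %d lines x %d pixels at %.6g Hz (%.3g s)\n",
              nrow(x$intensity), ncol(x$intensity), x$line_rate_hz,
              nrow(x$intensity) / x$line_rate_hz))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' @export
dim.linescan <- function(x) dim(x$intensity)

# Spatial illumination profile across the scanned line.
.spatial_profile <- function(n_pixels, profile = c("flat", "gaussian")) {
  profile <- match.arg(profile)
  if (profile == "flat") return(rep(1, n_pixels))
  x <- seq(-1, 1, length.out = n_pixels)
  exp(-x^2 / (2 * 0.4^2))
}

#' Simulate a line-scan recording of one paced cell
#'
#' Builds the deterministic transient waveform for the cell and draws each
#' pixel intensity independently from a Poisson distribution with
#' expectation `photon_gain * waveform(t_line) * spatial_profile(pixel) *
#' exp(-bleach_rate * t_line)`. With `noise = FALSE` the expectation itself
#' is returned (the infinite-photon limit), in which case the mean over
#' pixels equals the waveform exactly.
#'
#' @param cell A [transient_params()] object.
#' @param acq An [acquisition_params()] object.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param noise Draw Poisson photon noise (default `TRUE`).
#' @param profile Spatial profile across the line: `"flat"` (default) or
#'   `"gaussian"`.
#' @return A [linescan()] with the ground-truth parameters attached.
#' @examples
#' rec <- gen_linescan(transient_params(2.8, 169.5, 603.5),
#'                     acquisition_params(n_pixels = 16, n_lines = 500),
#'                     seed = 1)
#' dim(rec)
#' @export
gen_linescan <- function(cell, acq, seed = NULL, noise = TRUE,
                         profile = c("flat", "gaussian")) {
  stopifnot(inherits(cell, "transient_params"),
            inherits(acq, "acquisition_params"))
  profile <- match.arg(profile)
  n <- acq$n_lines
  p <- acq$n_pixels
  t <- (seq_len(n) - 1) / acq$line_rate_hz
  wave <- cell$baseline_f0 * .transient_ratio(t %% (1 / cell$pacing_hz), cell)
  if (acq$bleach_rate > 0) wave <- wave * exp(-acq$bleach_rate * t)
  lam_line <- acq$photon_gain * wave
  sp <- .spatial_profile(p, profile)
  if (!noise) {
    intensity <- outer(lam_line, sp)
  } else {
    if (!is.null(seed)) set.seed(seed)
    if (profile == "flat") {
      # lambda recycles over the line index (column-major), so draws land
      # in lines x pixels order without materializing the full lambda matrix
      intensity <- matrix(stats::rpois(n * p, lam_line), nrow = n)
    } else {
      intensity <- matrix(stats::rpois(n * p, outer(lam_line, sp)), nrow = n)
    }
  }
  linescan(intensity, line_rate_hz = acq$line_rate_hz,
           pixel_size_um = acq$scan_width_um / p,
           metadata = list(photon_gain = acq$photon_gain,
                           bleach_rate = acq$bleach_rate,
                           profile = profile, seed = seed,
                           noise = noise),
           truth = cell)
}

# Deterministic per-cell sub-seed derived from a population seed
# (computed in double precision to avoid 32-bit overflow, then reduced).
.cell_seed <- function(seed, i)
  as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)

#' Draw per-cell ground-truth parameters for a population
#'
#' Hierarchical draw emulating cells nested in differentiation batches:
#' each batch gets an additive Normal shift per metric
#' (`sd_between_diff`), each cell a Normal draw around the batch-shifted
#' mean with SD `cv_between_cell * mean`, truncated (by redrawing, at most
#' 100 times) to parameters that form a valid [transient_params()]. Cells
#' are assigned to batches as evenly as possible, in order.
#'
#' @param preset A [population_preset()].
#' @param n_cells Number of cells (>= `n_diff`). Defaults to the preset's
#'   `default_n_cells`.
#' @param seed Integer seed.
#' @return A data frame with one row per cell: `cell_id`, `diff_batch`,
#'   `amplitude_peak`, `rise_time_ms`, `decay50_ms`.
#' @export
gen_cell_params <- function(preset, n_cells = preset$default_n_cells, seed = 1) {
  stopifnot(inherits(preset, "population_preset"))
  k <- preset$n_diff
  if (n_cells < k) stop("n_cells must be >= n_diff")
  set.seed(seed)
  metrics <- c("amplitude_peak", "rise_time_ms", "decay50_ms")
  means <- unlist(preset$mean_params[metrics])
  batch_shift <- sapply(metrics, function(m)
    stats::rnorm(k, 0, preset$sd_between_diff[[m]]))
  batch_shift <- matrix(batch_shift, nrow = k,
                        dimnames = list(NULL, metrics))
  sizes <- rep(n_cells %/% k, k) + as.integer(seq_len(k) <= n_cells %% k)
  batch <- rep(seq_len(k), sizes)
  epoch_ms <- 1000 / preset$mean_params$pacing_hz
  draw_cell <- function(b) {
    for (try in 1:100) {
      v <- stats::rnorm(3, means + batch_shift[b, metrics],
                        preset$cv_between_cell[metrics] * means)
      names(v) <- metrics
      ok <- v[["amplitude_peak"]] >= 1 && v[["rise_time_ms"]] > 0 &&
        v[["decay50_ms"]] > 0 &&
        v[["rise_time_ms"]] + 2 * v[["decay50_ms"]] < epoch_ms
      if (ok) return(v)
    }
    bad <- if (v[["amplitude_peak"]] < 1) "amplitude_peak"
      else if (v[["rise_time_ms"]] <= 0) "rise_time_ms"
      else "decay50_ms"
    stop(sprintf("could not draw a valid cell after 100 tries (metric: %s)", bad))
  }
  vals <- t(vapply(batch, draw_cell, numeric(3)))
  data.frame(cell_id = sprintf("cell_%03d", seq_len(n_cells)),
             diff_batch = batch,
             amplitude_peak = vals[, 1],
             rise_time_ms = vals[, 2],
             decay50_ms = vals[, 3])
}

#' Simulate a population of line-scan recordings
#'
#' Draws per-cell parameters with [gen_cell_params()] and renders one
#' recording per cell with [gen_linescan()], using a deterministic per-cell
#' sub-seed so that any cell can be regenerated independently.
#'
#' Holding many full-size recordings in memory is expensive; for
#' population-scale analysis use [run_imaging_arm()], which generates and
#' measures one cell at a time using the identical seed path.
#'
#' @inheritParams gen_cell_params
#' @param acq An [acquisition_params()] object.
#' @param noise Draw Poisson photon noise (default `TRUE`).
#' @return A list with `cells` (the ground-truth data frame, including the
#'   batch labels) and `recordings` (a list of [linescan()] objects).
#' @export
gen_cell_population <- function(preset, n_cells = preset$default_n_cells,
                                acq = acquisition_params(), seed = 1,
                                noise = TRUE) {
  cells <- gen_cell_params(preset, n_cells, seed)
  recordings <- lapply(seq_len(nrow(cells)), function(i) {
    cp <- transient_params(cells$amplitude_peak[i], cells$rise_time_ms[i],
                           cells$decay50_ms[i],
                           baseline_f0 = preset$mean_params$baseline_f0,
                           pacing_hz = preset$mean_params$pacing_hz)
    rec <- gen_linescan(cp, acq, seed = .cell_seed(seed, i), noise = noise)
    rec$metadata$cell_id <- cells$cell_id[i]
    rec$metadata$diff_batch <- cells$diff_batch[i]
    rec
  })
  list(cells = cells, recordings = recordings)
}
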