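#' Write a line-scan recording to disk
#'
#' Writes the intensity array either as a single-page 16-bit grayscale TIFF
#' (rows = lines, columns = pixels) or as CSV (one line per row, no
#' header), plus a JSON sidecar (`<path>.json`) carrying the acquisition
#' metadata and, if present, the ground truth. The TIFF route requires
#' integer intensities in 0..65535 (photon counts); arbitrary real-valued
#' data (e.g. noiseless expectations) round-trip through CSV.
#'
#' @param rec A [linescan()].
#' @param path Output file path.
#' @param format `"tiff"` or `"csv"`; default guessed from the extension.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_linescan <- function(rec, path, format = c("auto", "tiff", "csv"),
                           sidecar = TRUE) {
  stopifnot(inherits(rec, "linescan"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tiff"
  m <- rec$intensity
  if (format == "tiff") {
    if (any(m != round(m)) || max(m) > 65535)
      stop("TIFF output requires integer intensities in 0..65535; use CSV")
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  } else {
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  if (sidecar) {
    meta <- list(line_rate_hz = rec$line_rate_hz,
                 pixel_size_um = rec$pixel_size_um,
                 n_lines = nrow(m), n_pixels = ncol(m),
                 metadata = rec$metadata)
    if (!is.null(rec$truth)) meta$truth <- unclass(rec$truth)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a line-scan recording
#'
#' Reads a recording written by [write_linescan()] (or any single-page
#' grayscale TIFF / headerless CSV with lines as rows). The line rate is
#' taken from the JSON sidecar if present, otherwise it must be supplied --
#' without it the time axis is undefined.
#'
#' @param path File path.
#' @param format `"tiff"` or `"csv"`; default guessed from the extension.
#' @param line_rate_hz Line rate in Hz; overrides the sidecar.
#' @param pixel_size_um Pixel size; overrides the sidecar.
#' @return A [linescan()].
#' @export
read_linescan <- function(path, format = c("auto", "tiff", "csv"),
                          line_rate_hz = NULL, pixel_size_um = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tiff"
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(line_rate_hz)) line_rate_hz <- meta$line_rate_hz
  if (is.null(line_rate_hz))
    stop("line_rate_hz missing: no sidecar and none supplied; time axis undefined")
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (format == "tiff") {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) != 2)
      stop("expected a single-page grayscale (2-D) image, got ",
           paste(dim(m), collapse = " x "))
    m <- round(m * 65535)
  } else {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    if (!is.numeric(m)) stop("CSV did not parse as a numeric matrix")
  }
  truth <- NULL
  if (!is.null(meta$truth))
    truth <- transient_params(meta$truth$amplitude_peak,
                              meta$truth$rise_time_ms,
                              meta$truth$decay50_ms,
                              meta$truth$baseline_f0,
                              meta$truth$pacing_hz)
  linescan(m, line_rate_hz = line_rate_hz,
           pixel_size_um = if (is.null(pixel_size_um)) NA_real_ else pixel_size_um,
           metadata = if (is.null(meta$metadata)) list() else meta$metadata,
           truth = truth)
}

#' Export a trace as two-column CSV
#'
#' @param trace A [fluor_trace()].
#' @param path Output path; columns `time_s`, `value`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fluor_trace"))
  utils::write.csv(data.frame(time_s = trace$time_s, value = trace$value),
                   path, row.names = FALSE)
  invisible(path)
}
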