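# Independent oracles used to pin expected values. These deliberately take
# the slow, literal route (explicit polynomial fits, enumeration, raw
# sums of squares) so they stay independent of the implementation paths
# they check.

# Savitzky-Golay by explicit local least-squares polynomial fits, with
# nearest-full-window polynomial extrapolation at the edges.
sg_brute <- function(x, order, neighbors) {
  n <- length(x)
  w <- 2 * neighbors + 1
  out <- numeric(n)
  fit_window <- function(center) {
    idx <- (center - neighbors):(center + neighbors)
    off <- idx - center
    stats::lm.fit(outer(off, 0:order, "^"), x[idx])$coefficients
  }
  for (i in (neighbors + 1):(n - neighbors)) out[i] <- fit_window(i)[1]
  cf_first <- fit_window(neighbors + 1)
  cf_last <- fit_window(n - neighbors)
  for (i in 1:neighbors) {
    off <- i - (neighbors + 1)
    out[i] <- sum(cf_first * off^(0:order))
    off2 <- (n - neighbors + i) - (n - neighbors)
    out[n - neighbors + i] <- sum(cf_last * off2^(0:order))
  }
  out
}

# Benjamini-Hochberg step-up, written out literally.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# All global alignments of two short sequences, by recursion; returns the
# maximal score under match/mismatch/gap scoring.
nw_enum_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  av <- if (nchar(a)) strsplit(a, "")[[1]] else character(0)
  bv <- if (nchar(b)) strsplit(b, "")[[1]] else character(0)
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (av[i] == bv[j]) match else mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

# One-way random-effects ANOVA pieces from raw sums of squares.
anova_brute <- function(values, batch) {
  batch <- as.factor(batch)
  k <- nlevels(batch)
  n_i <- as.numeric(table(batch))
  N <- length(values)
  means <- tapply(values, batch, mean)
  list(ms_between = sum(n_i * (means - mean(values))^2) / (k - 1),
       ms_within = sum((values - means[batch])^2) / (N - k),
       n0 = (N - sum(n_i^2) / N) / (k - 1))
}

# Small acquisition used throughout the tests (full line rate, short and
# narrow so a single cell renders in milliseconds).
small_acq <- function(n_lines = 4300, n_pixels = 16, ...) {
  acquisition_params(n_lines = n_lines, n_pixels = n_pixels, ...)
}

# Noiseless single-epoch measurement chain on a generated waveform.
measure_noiseless <- function(params, order = 6, neighbors = 10,
                              duration = 1 / params$pacing_hz) {
  tr <- gen_transient_waveform(params, dt = 1 / 1057.7, duration = duration)
  tr <- smooth_trace(tr, order, neighbors)
  f0 <- detect_baseline(tr)
  tr <- normalize_f0(tr, f0)
  measure_transient(tr, baseline = detect_baseline(tr))
}
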