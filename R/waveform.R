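# Fraction of the sigmoidal upstroke that lies between the 15%-height
# crossing and the peak. With a raised-cosine upstroke the 15% crossing
# happens at acos(1 - 2*0.15)/pi of the upstroke duration, so dividing the
# target rise time by this fraction gives the full upstroke duration.
.ONSET_FRAC <- 0.15
.RISE_FRACTION <- 1 - acos(1 - 2 * .ONSET_FRAC) / pi

# Internal geometry of one transient epoch, all in seconds.
# The decay is monoexponential with tau = decay50 / ln 2, except for
# (i) a short C1 cubic cap just after the peak so the waveform has a
# continuous derivative there (an uncapped cosine-to-exponential joint has a
# slope jump that biases the smoothed peak location), and (ii) a smooth
# return to baseline once the transient has decayed to a small fraction of
# its height, so that every epoch ends with a genuine resting segment for
# the baseline estimator. Neither modification touches the waveform between
# 15% and 95% of the height, so onset, peak and half-decay crossings are
# exact.
.epoch_geometry <- function(params) {
  epoch <- 1 / params$pacing_hz
  rise_s <- params$rise_time_ms / 1000
  d50_s <- params$decay50_ms / 1000
  t_up <- rise_s / .RISE_FRACTION
  tau <- d50_s / log(2)
  ramp <- 0.1
  # exponential runs until t_cut after the peak, then ramps to baseline;
  # aim to leave >= 25% of the epoch at rest, but never cut above 43% of
  # the height (t_cut >= 1.2 * decay50 keeps the half-decay crossing on the
  # pure exponential) and never below 5% (t_cut <= 3 * tau).
  t_cut <- max(1.2 * d50_s, min(3 * tau, 0.75 * epoch - t_up - ramp))
  ramp <- max(0, min(ramp, epoch - t_up - t_cut))
  # C1 cap: h(d) = 1 + c2 d^2 + c3 d^3 on [0, eps] matching the exponential
  # value and slope at eps, with h(0) = 1, h'(0) = 0.
  eps <- 0.03 * tau
  u <- exp(-eps / tau)
  c2 <- (3 * (u - 1) + eps * u / tau) / eps^2
  c3 <- (u - 1 - c2 * eps^2) / eps^3
  list(epoch = epoch, t_up = t_up, tau = tau, t_cut = t_cut, ramp = ramp,
       eps = eps, c2 = c2, c3 = c3, f_cut = exp(-t_cut / tau))
}

# F/F0 ratio of the waveform at epoch phase `phase` (seconds, vectorized).
.transient_ratio <- function(phase, params, geom = .epoch_geometry(params)) {
  a <- params$amplitude_peak
  if (a == 1) return(rep(1, length(phase)))
  r <- numeric(length(phase))
  up <- phase < geom$t_up
  r[up] <- 0.5 * (1 - cos(pi * phase[up] / geom$t_up))
  d <- phase - geom$t_up
  cap <- !up & d < geom$eps
  r[cap] <- 1 + geom$c2 * d[cap]^2 + geom$c3 * d[cap]^3
  ex <- !up & !cap & d < geom$t_cut
  r[ex] <- exp(-d[ex] / geom$tau)
  rp <- !up & !cap & !ex & d < geom$t_cut + geom$ramp
  if (any(rp) && geom$ramp > 0)
    r[rp] <- geom$f_cut * 0.5 * (1 + cos(pi * (d[rp] - geom$t_cut) / geom$ramp))
  1 + (a - 1) * r
}

#' Generate a noiseless transient waveform
#'
#' Deterministic fluorescence time course of a paced cell: per pacing epoch
#' a resting baseline, a raised-cosine upstroke whose 15%-height
#' crossing-to-peak interval equals `rise_time_ms` exactly, and a
#' monoexponential decay with time constant `decay50_ms / ln 2`, so that the
#' peak-to-half-height interval equals `decay50_ms` exactly. Late in each
#' epoch the residual tail is smoothly ramped back to baseline so the cell
#' genuinely rests between stimuli.
#'
#' @param params A [transient_params()] object.
#' @param dt Sampling interval in seconds (> 0), e.g. `1 / line_rate_hz`.
#' @param duration Total duration in seconds (at least one pacing epoch).
#' @return A [fluor_trace()] in raw fluorescence units (baseline at
#'   `baseline_f0`).
#' @examples
#' p <- transient_params(2.8, 169.5, 603.5)
#' tr <- gen_transient_waveform(p, dt = 1 / 1057.7, duration = 4)
#' max(tr$value) / p$baseline_f0   # 2.8
#' @export
gen_transient_waveform <- function(params, dt, duration) {
  stopifnot(inherits(params, "transient_params"))
  if (dt <= 0) stop("dt must be > 0")
  epoch <- 1 / params$pacing_hz
  if (duration < epoch - 1e-12)
    stop("duration must cover at least one pacing epoch")
  n <- floor(duration / dt + 1e-9)
  t <- (seq_len(n) - 1) * dt
  geom <- .epoch_geometry(params)
  value <- params$baseline_f0 * .transient_ratio(t %% epoch, params, geom)
  fluor_trace(value, line_rate_hz = 1 / dt)
}
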