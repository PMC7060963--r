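test_that("baseline detection: constants, shifts, generator truth", {
  expect_equal(detect_baseline(fluor_trace(rep(3.2, 150), 100)), 3.2)
  expect_error(detect_baseline(fluor_trace(rep(0, 150), 100)), "dynamic range")
  expect_error(detect_baseline(fluor_trace(rep(1, 50), 100)), "short")
  p <- transient_params(2.8, 169.5, 603.5, baseline_f0 = 120)
  tr <- gen_transient_waveform(p, dt = 1 / 1057.7, duration = 4)
  expect_equal(detect_baseline(tr), 120)
  tr2 <- tr; tr2$value <- tr$value + 13      # shift equivariance
  expect_equal(detect_baseline(tr2), 133)
})

test_that("epoch segmentation matches the pacing arithmetic", {
  tr <- fluor_trace(rep(1, 20000), line_rate_hz = 1057.7)
  w <- segment_transients(tr, pacing_hz = 0.25)
  expect_equal(nrow(w), 4)                   # floor(18.907 s / 4 s)
  expect_equal(w$start_index[1], 1)
  # offset of half an epoch loses the trailing partial epoch
  w2 <- segment_transients(tr, 0.25, stim_offset_s = 2)
  expect_equal(nrow(w2), 4)
  w3 <- segment_transients(tr, 0.25, stim_offset_s = 3)
  expect_equal(nrow(w3), 3)
  expect_error(segment_transients(tr, pacing_hz = 2000), "faster")
  expect_error(segment_transients(fluor_trace(rep(1, 100), 100), 0.25),
               "no full pacing epoch")
})

test_that("triangle transient has closed-form rise and decay metrics", {
  # baseline 1, linear rise to 1 + h over w, linear fall back over w:
  # measured rise = 0.85 w (15% threshold), decay50 = 0.5 w
  dt <- 0.001; w <- 0.2; h <- 1.5
  up <- seq(0, h, length.out = w / dt + 1)
  tri <- c(rep(0, 300), up, rev(up)[-1], rep(0, 1000)) + 1
  tr <- fluor_trace(tri, line_rate_hz = 1 / dt)
  m <- measure_transient(tr, baseline = 1)
  expect_equal(m$amplitude, 1 + h)
  expect_equal(m$rise_time_ms, 0.85 * w * 1000, tolerance = 1e-6)
  expect_equal(m$decay50_ms, 0.5 * w * 1000, tolerance = 1e-6)
})

test_that("monoexponential decay measures decay50 = tau * ln 2", {
  dt <- 0.001; tau <- 0.4
  t <- seq(0, 3, by = dt)
  v <- 1 + 2 * exp(-t / tau)
  tr <- fluor_trace(c(rep(1, 200), 1 + 2 * t[t < 0.05] / 0.05, v), 1 / dt)
  m <- measure_transient(tr, baseline = 1)
  expect_lt(abs(m$decay50_ms - tau * log(2) * 1000), dt * 1000)
})

test_that("epochs without a transient or half-decay are excluded", {
  flat <- fluor_trace(rep(1, 500) + 1e-4 * sin(1:500), 100)
  m <- measure_transient(flat, baseline = 1)
  expect_true(is_excluded(m))
  expect_equal(m$reason, "no transient")
  # rises but never decays to half within the window
  ramp <- fluor_trace(c(rep(1, 100), seq(1, 3, length.out = 400)), 100)
  m2 <- measure_transient(ramp, baseline = 1)
  expect_true(is_excluded(m2))
  expect_equal(m2$reason, "no half-decay within epoch")
})

test_that("noiseless KO-preset epoch recovers the printed KO metrics", {
  m <- measure_noiseless(ca_preset("KO")$mean_params)
  period_ms <- 1000 / 1057.7
  expect_equal(m$amplitude, 3.5, tolerance = 0.01)
  expect_lt(abs(m$rise_time_ms - 199.0), period_ms)
  expect_lt(abs(m$decay50_ms - 460.8), period_ms)
})

test_that("noiseless end-to-end recovery over the parameter grid", {
  # times within 2 line periods, amplitude within 1%
  period_ms <- 1000 / 1057.7
  for (a in c(1.5, 2.8, 5)) for (r in c(80, 200, 400)) for (d in c(200, 550, 900)) {
    m <- measure_noiseless(transient_params(a, r, d))
    expect_lt(abs(m$amplitude - a) / a, 0.01)
    expect_lt(abs(m$rise_time_ms - r), 2 * period_ms)
    expect_lt(abs(m$decay50_ms - d), 2 * period_ms)
  }
})

test_that("measured decay50 increases strictly with generator decay50", {
  d <- seq(250, 850, by = 100)
  got <- vapply(d, function(x)
    measure_noiseless(transient_params(3, 150, x))$decay50_ms, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("smoothing shifts the noiseless peak by at most one line period", {
  dt <- 1 / 1057.7
  for (g in c("WT", "KO", "WT_HELHO", "KO_HELHO")) {
    p <- ca_preset(g)$mean_params
    tr <- gen_transient_waveform(p, dt = dt, duration = 4)
    sm <- smooth_trace(tr)
    expect_lte(abs(which.max(sm$value) - which.max(tr$value)), 1)
  }
})

test_that("cell summaries average transients and respect exclusions", {
  mk <- function(rise) {
    m <- data.frame(t_start_s = 0, t_peak_s = 0.1, amplitude = 2,
                    rise_time_ms = rise, decay50_ms = 300, baseline = 1)
    class(m) <- c("transient_metrics", "data.frame")
    m
  }
  s <- summarize_cell(list(mk(100), mk(200), mk(300), mk(400)), "c1", 2)
  expect_equal(s$rise_time_ms, 250)
  expect_equal(s$n_transients_used, 4)
  excl <- measure_transient(fluor_trace(rep(1, 500) + 1e-4 * sin(1:500), 100),
                            baseline = 1)
  s2 <- summarize_cell(list(mk(100), excl, mk(300)), "c1", 2)
  expect_equal(s2$n_transients_used, 2)
  expect_equal(s2$rise_time_ms, 200)
  s3 <- summarize_cell(list(excl, excl), "c1", 2)
  expect_true(is_excluded(s3))
  expect_equal(s3$reason, "no valid transients")
  # four identical transients summarize to the single transient
  s4 <- summarize_cell(list(mk(150), mk(150), mk(150), mk(150)))
  expect_equal(s4$rise_time_ms, 150)
})

test_that("time metrics are invariant under intensity scaling", {
  p <- transient_params(3.2, 180, 500)
  rec <- gen_linescan(p, small_acq(), seed = 6)
  r1 <- analyze_recording(rec)
  rec2 <- rec; rec2$intensity <- rec$intensity * 5
  r2 <- analyze_recording(rec2)
  expect_equal(r2$summary$rise_time_ms, r1$summary$rise_time_ms)
  expect_equal(r2$summary$decay50_ms, r1$summary$decay50_ms)
  expect_equal(r2$summary$amplitude, r1$summary$amplitude)  # post-normalization
})

test_that("metrics are invariant under stimulus-grid translation", {
  p <- transient_params(3, 170, 450, pacing_hz = 0.5)
  acq <- small_acq(n_lines = 8500)
  rec <- gen_linescan(p, acq, noise = FALSE)
  tr <- normalize_f0(smooth_trace(extract_trace(rec)), 100)
  m0 <- measure_transient(tr, segment_transients(tr, 0.5)[2, ], baseline = 1)
  # shift the trace by half an epoch and tell the analyzer about it
  v <- tr$value
  shift <- round(1 * tr$line_rate_hz)
  tr2 <- fluor_trace(c(rep(1, shift), v[1:(length(v) - shift)]),
                     tr$line_rate_hz, normalized = TRUE, f0 = 100)
  m2 <- measure_transient(tr2, segment_transients(tr2, 0.5,
                                                  stim_offset_s = 1)[2, ],
                          baseline = 1)
  expect_equal(m2$rise_time_ms, m0$rise_time_ms, tolerance = 1e-6)
  expect_equal(m2$decay50_ms, m0$decay50_ms, tolerance = 1e-6)
  expect_equal(m2$amplitude, m0$amplitude, tolerance = 1e-12)
})
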