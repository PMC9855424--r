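# Calcium-transient analysis: dF/F0, beat detection, segmentation,
# decay fitting, summaries.

test_that("compute_dff zeroes a constant trace and is scale-invariant", {
  t <- seq(0, 4, by = 0.02)
  flat <- ca_trace(t, rep(3, length(t)))
  expect_true(all(compute_dff(flat)$values == 0))
  tr <- make_calcium_trace(duration_s = 10, fs_hz = 50, diastolic = 2,
                           signal_kind = "raw")
  d1 <- compute_dff(tr)
  tr2 <- tr
  tr2$values <- 5 * tr$values
  expect_equal(compute_dff(tr2)$values, d1$values, tolerance = 1e-12)
  neg <- ca_trace(t, rep(-1, length(t)))
  expect_error(compute_dff(neg), "background")
})

test_that("dF/F0 amplitude recovers amplitude/diastolic from the generator", {
  amp <- 0.8; dia <- 2
  tr <- make_calcium_trace(duration_s = 30, fs_hz = 50, interval_s = 3,
                           ttp_s = 0.3, tau_s = 0.3, amplitude = amp,
                           diastolic = dia, signal_kind = "raw")
  ana <- analyze_calcium_trace(compute_dff(tr))
  expect_equal(ana$summary$mean_amplitude, amp / dia, tolerance = 0.02)
})

test_that("compute_ratio validates grids and denominators", {
  t <- seq(0, 4, by = 0.02)
  a <- ca_trace(t, rep(4, length(t)))
  b <- ca_trace(t, rep(2, length(t)))
  expect_equal(compute_ratio(a, b)$values, rep(2, length(t)))
  bad <- ca_trace(t, c(rep(2, 100), 0.5, rep(2, length(t) - 101)))
  expect_error(compute_ratio(a, bad, bg380 = 1), "sample 101")
  t2 <- seq(0.5, 4.5, by = 0.02)
  expect_error(compute_ratio(a, ca_trace(t2, rep(2, length(t2)))), "grid")
})

test_that("detect_beats finds every paced beat at the true peak sample", {
  tr <- make_calcium_trace(duration_s = 61, fs_hz = 50, interval_s = 2)
  th <- synthetic_truth(tr)$truth
  pk <- detect_beats(tr)
  expect_length(pk, length(th$peaks_s))
  expect_true(all(abs(pk - th$peaks_s) <= 1 / tr$fs_hz + 1e-9))
})

test_that("monotone ramps and flat traces yield no peaks", {
  t <- seq(0, 4, by = 0.02)
  expect_length(detect_beats(ca_trace(t, t)), 0)
  expect_length(detect_beats(ca_trace(t, rep(1, length(t)))), 0)
})

test_that("peak count is noise-robust at moderate SNR", {
  counts <- vapply(0:49, function(s) {
    tr <- make_calcium_trace(duration_s = 30, fs_hz = 50, interval_s = 2,
                             noise_sigma = 0.2, seed = s)
    length(detect_beats(tr))
  }, numeric(1))
  expect_true(all(counts == counts[1]))
})

test_that("segmentation recovers onset, amplitude and diastolic level", {
  tr <- make_calcium_trace(duration_s = 45, fs_hz = 50, interval_s = 3,
                           ttp_s = 0.3, tau_s = 0.3, amplitude = 1,
                           diastolic = 1)
  th <- synthetic_truth(tr)$truth
  beats <- segment_transients(tr, detect_beats(tr))
  expect_equal(nrow(beats), length(th$onsets_s))
  # onset = truth onset + the half-cosine 10% crossing, within 1 sample
  crossing <- acos(0.8) / pi * 0.3
  expect_true(all(abs(beats$onset_s - (th$onsets_s + crossing)) <=
                    1 / tr$fs_hz + 1e-9))
  expect_equal(beats$amplitude, rep(1, nrow(beats)), tolerance = 0.01)
  expect_equal(beats$diastolic, rep(1, nrow(beats)), tolerance = 0.01)
  # windows are disjoint and ordered
  expect_true(all(diff(beats$win_start) > 0))
  expect_true(all(beats$win_end[-nrow(beats)] < beats$win_start[-1]))
})

test_that("a peak at the trace start is dropped from segmentation", {
  tr <- make_calcium_trace(duration_s = 10, fs_hz = 50, interval_s = 2)
  pk <- detect_beats(tr)
  n_ok <- nrow(segment_transients(tr, pk))
  # prepend a bogus peak at the very first sample: no pre-peak segment
  pk_bad <- structure(c(tr$time_s[1], as.numeric(pk)),
                      index = c(1L, attr(pk, "index")))
  expect_message(beats <- segment_transients(tr, pk_bad), "dropped")
  expect_equal(nrow(beats), n_ok)
})

test_that("decay tau is recovered and offset-invariant", {
  tr <- make_calcium_trace(duration_s = 45, fs_hz = 50, interval_s = 3,
                           ttp_s = 0.3, tau_s = 0.4)
  ana <- analyze_calcium_trace(tr)
  expect_true(all(abs(ana$beats$tau_s - 0.4) < 0.004))
  expect_true(all(ana$beats$fit_r2 > 0.999))
  # constant offset leaves tau unchanged (three-parameter model)
  tr2 <- tr
  tr2$values <- tr$values + 10
  ana2 <- analyze_calcium_trace(tr2)
  expect_equal(ana2$beats$tau_s, ana$beats$tau_s, tolerance = 1e-6)
})

test_that("tau estimation tolerates 5% noise (median error < 5%)", {
  errs <- vapply(0:49, function(s) {
    tr <- make_calcium_trace(duration_s = 30, fs_hz = 50, interval_s = 2,
                             ttp_s = 0.3, tau_s = 0.4, noise_sigma = 0.05,
                             seed = s)
    ana <- analyze_calcium_trace(tr)
    abs(stats::median(ana$beats$tau_s, na.rm = TRUE) - 0.4) / 0.4
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("tau is robust to slow linear drift (< 3% shift)", {
  base <- make_calcium_trace(duration_s = 30, fs_hz = 50, interval_s = 2,
                             ttp_s = 0.3, tau_s = 0.4)
  drift <- make_calcium_trace(duration_s = 30, fs_hz = 50, interval_s = 2,
                              ttp_s = 0.3, tau_s = 0.4,
                              drift_per_s = 0.01)
  t0 <- mean(analyze_calcium_trace(base)$beats$tau_s, na.rm = TRUE)
  t1 <- mean(analyze_calcium_trace(drift)$beats$tau_s, na.rm = TRUE)
  expect_lt(abs(t1 - t0) / t0, 0.03)
})

test_that("too-short decays report a reason code instead of tau", {
  tr <- make_calcium_trace(duration_s = 45, fs_hz = 50, interval_s = 3)
  beats <- segment_transients(tr, detect_beats(tr))
  b <- beats[1, ]
  b$win_end <- b$peak_idx + 3L
  f <- fit_decay_tau(tr, b)
  expect_true(is.na(f$tau_s))
  expect_equal(f$note, "too_few_samples")
})

test_that("summary metrics: paced rate, interval SD, irregular fraction", {
  tr <- make_calcium_trace(duration_s = 60, fs_hz = 50, interval_s = 2)
  s <- analyze_calcium_trace(tr)$summary
  expect_equal(s$beat_rate_hz, 0.5, tolerance = 1e-9)
  expect_equal(s$beat_rate_bpm, 60 * s$beat_rate_hz)
  expect_identical(s$interval_sd_s, 0)
  expect_identical(s$irregular_event_fraction, 0)
})

test_that("interval SD estimates the generator's jitter SD", {
  sds <- vapply(0:49, function(s) {
    tr <- make_calcium_trace(duration_s = 202, fs_hz = 20, interval_s = 2,
                             interval_jitter_sd_s = 0.1, ttp_s = 0.25,
                             tau_s = 0.35, seed = s)
    analyze_calcium_trace(tr)$summary$interval_sd_s
  }, numeric(1))
  expect_lt(abs(mean(sds) - 0.1), 0.02)
})

test_that("interval SD grows monotonically with generator jitter", {
  mean_sd <- vapply(c(0.02, 0.05, 0.1, 0.2), function(jv) {
    mean(vapply(0:49, function(s) {
      tr <- make_calcium_trace(duration_s = 60, fs_hz = 25, interval_s = 2,
                               interval_jitter_sd_s = jv, ttp_s = 0.25,
                               tau_s = 0.35, seed = s)
      analyze_calcium_trace(tr)$summary$interval_sd_s
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sd) > 0))
})

test_that("one doubled interval among 20 gives irregular fraction 1/19", {
  onsets <- cumsum(c(0, rep(2, 18), 4))  # 20 beats, last interval doubled
  t <- seq(0, 46, by = 0.02)
  v <- rep(1, length(t))
  for (o in onsets) {
    ir <- t >= o & t <= o + 0.3
    v[ir] <- v[ir] + 0.5 * (1 - cos(pi * (t[ir] - o) / 0.3))
    id <- t > o + 0.3 & t < o + 1.9
    v[id] <- v[id] + exp(-(t[id] - o - 0.3) / 0.3)
  }
  tr <- ca_trace(t, v)
  s <- analyze_calcium_trace(tr)$summary
  expect_equal(s$n_beats, 20)
  expect_equal(s$irregular_event_fraction, 1 / 19)
})

test_that("summaries handle 0 and 1 beats gracefully", {
  t <- seq(0, 4, by = 0.02)
  flat <- ca_trace(t, rep(1, length(t)))
  s0 <- summarize_trace(flat, segment_transients(flat, detect_beats(flat)))
  expect_equal(s0$n_beats, 0)
  expect_true(is.na(s0$beat_rate_hz))
  expect_true(is.na(s0$interval_sd_s))
  one <- rep(1, length(t))
  ir <- t >= 1 & t <= 1.3
  one[ir] <- 1 + 0.5 * (1 - cos(pi * (t[ir] - 1) / 0.3))
  one[t > 1.3] <- 1 + exp(-(t[t > 1.3] - 1.3) / 0.3)
  tr1 <- ca_trace(t, one)
  s1 <- summarize_trace(tr1, segment_transients(tr1, detect_beats(tr1)))
  expect_equal(s1$n_beats, 1)
  expect_true(is.na(s1$beat_rate_hz))
})

test_that("ratio and dF/F0 pipelines agree on beat timing", {
  tr <- make_calcium_trace(duration_s = 30, fs_hz = 50, interval_s = 2,
                           interval_jitter_sd_s = 0.08, ttp_s = 0.3,
                           tau_s = 0.4, seed = 12)
  pair <- make_fura2_pair(tr, f380_baseline = 100)
  ratio <- compute_ratio(pair$f340, pair$f380)
  # a raw single-dye trace proportional to the same underlying signal
  raw <- ca_trace(tr$time_s, 500 * tr$values, signal_kind = "raw")
  pk_ratio <- detect_beats(ratio)
  pk_dff <- detect_beats(compute_dff(raw))
  expect_equal(as.numeric(pk_ratio), as.numeric(pk_dff))
})

test_that("noiseless end-to-end recovery of all kinetic parameters", {
  ttp <- 0.3; tau <- 0.3; amp <- 1.2; dia <- 1.5
  tr <- make_calcium_trace(duration_s = 45, fs_hz = 50, interval_s = 3,
                           ttp_s = ttp, tau_s = tau, amplitude = amp,
                           diastolic = dia)
  s <- analyze_calcium_trace(tr)$summary
  dt <- 1 / tr$fs_hz
  expect_lt(abs(s$mean_ttp_s - expected_measured_ttp(ttp)), dt)
  expect_lt(abs(s$mean_tau_s - tau) / tau, 0.01)
  expect_lt(abs(s$mean_amplitude - amp) / amp, 0.01)
  expect_lt(abs(s$mean_diastolic - dia) / dia, 0.01)
  expect_equal(s$beat_rate_hz, 1 / 3, tolerance = 1e-9)
})
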