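# FFT power distribution: calibration, period recovery, oracle
# equivalence, scale behavior, degeneracies.

test_that("unit cosine calibrates to peak power 1.0 at its period", {
  for (period in c(1.6, 2.0, 2.7, 3.3)) {
    p <- make_striation_profile(period, 0.1, 40)
    s <- fft_power_spectrum(p)
    expect_lt(abs(s$main_peak_power - 1), 0.02)
    # one zero-padded frequency bin of slack on the recovered period
    df <- 1 / (4 * length(p$intensity) * p$pixel_um)
    expect_lt(abs(1 / s$main_period_um - 1 / period), df + 1e-12)
    expect_true(s$main_period_um >= s$search_band_um[1] &&
                  s$main_period_um <= s$search_band_um[2])
  }
})

test_that("main peak power is the power at the main period's frequency", {
  p <- ctrl_profile(seed = 4)
  s <- fft_power_spectrum(p)
  i <- which.min(abs(s$frequency_per_um - 1 / s$main_period_um))
  expect_equal(s$power[i], s$main_peak_power)
  expect_true(all(s$power >= 0))
})

test_that("FFT path agrees with the brute-force periodogram oracle", {
  p <- make_striation_profile(2.0, 0.25, 16, jitter_sigma = 0.1,
                              noise_sigma = 0.3, seed = 11)
  expect_length(p$intensity, 64L)
  s <- fft_power_spectrum(p, c(1, 5))
  oracle <- periodogram_oracle(p, s$frequency_per_um)
  expect_equal(s$power, oracle, tolerance = 1e-9)
})

test_that("intensity scaling contracts: raw score linear, normalized flat", {
  p <- ctrl_profile(seed = 9)
  s1 <- fft_power_spectrum(p)
  p2 <- p
  p2$intensity <- 3.5 * p$intensity
  s2 <- fft_power_spectrum(p2)
  expect_equal(regularity_score(s2), 3.5 * regularity_score(s1),
               tolerance = 1e-9)
  expect_equal(regularity_score(s2, normalize = "amplitude"),
               regularity_score(s1, normalize = "amplitude"),
               tolerance = 1e-9)
})

test_that("constant profile yields a flagged no-periodicity spectrum", {
  p <- striation_profile(rep(5, 64), 0.1)
  s <- fft_power_spectrum(p)
  expect_true(s$no_periodicity)
  expect_true(is.na(s$main_period_um))
  expect_warning(sc <- regularity_score(s), "no periodicity")
  expect_equal(sc, 0)
})

test_that("empty search band after Nyquist clipping is rejected", {
  p <- make_striation_profile(2.0, 0.5, 12)
  expect_error(fft_power_spectrum(p, c(0.2, 0.9)), "band")
})

test_that("white-noise profiles score far below a cosine", {
  # frozen from a 50-seed Monte-Carlo of this exact protocol: mean 0.249,
  # max 0.364 (cosine scores 1.0); see methods vignette for conditions
  scores <- vapply(0:49, function(s) {
    p <- make_striation_profile(2.0, 0.1, 40, amplitude = 0, baseline = 10,
                                noise_sigma = 1, seed = s)
    regularity_score(fft_power_spectrum(p))
  }, numeric(1))
  expect_lt(mean(scores), 0.3)
  expect_lt(max(scores), 0.5)
})

test_that("disease-like disorder lowers peak power: jitter monotonicity", {
  mean_power <- vapply(c(0.1, 0.2, 0.4, 0.8), function(js) {
    mean(vapply(0:49, function(s) {
      p <- make_striation_profile(2.0, 0.1, 40, jitter_sigma = js,
                                  noise_sigma = 0.1, seed = s)
      fft_power_spectrum(p)$main_peak_power
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_power) < 0))
})

test_that("KO-like fixtures score below Ctrl-like fixtures on average", {
  ctrl <- vapply(0:19, function(s) {
    regularity_score(fft_power_spectrum(ctrl_profile(seed = s,
                                                     jitter = 0.05)))
  }, numeric(1))
  ko <- vapply(0:19, function(s) {
    regularity_score(fft_power_spectrum(ko_profile(seed = s,
                                                   jitter = 0.25)))
  }, numeric(1))
  expect_lt(mean(ko), mean(ctrl))
})

test_that("profile extraction matches the generator within tolerance", {
  p <- make_striation_profile(2.0, 0.1, 40, jitter_sigma = 0.03, seed = 6)
  img <- make_striation_image(p, n_rows = 11, seed = 6)
  tl <- synthetic_truth(img)$truth$line
  prof <- profile_from_image(img, tl$p0, tl$p1, 1, 0.1)
  rms <- sqrt(mean((prof$intensity - p$intensity)^2))
  expect_lt(rms, 0.01 * diff(range(p$intensity)))
  # identical rows: width averaging is a no-op
  img0 <- make_striation_image(p, n_rows = 11)
  prof1 <- profile_from_image(img0, tl$p0, tl$p1, 1, 0.1)
  prof3 <- profile_from_image(img0, tl$p0, tl$p1, 3, 0.1)
  expect_equal(prof3$intensity, prof1$intensity, tolerance = 1e-12)
  # constant image -> constant profile
  flat <- matrix(7, 20, 40)
  pf <- profile_from_image(flat, c(1, 9), c(35, 9), 1, 0.1)
  expect_true(all(pf$intensity == 7))
  # out-of-bounds and too-short lines are rejected
  expect_error(profile_from_image(flat, c(1, 9), c(60, 9), 1, 0.1),
               "outside")
  expect_error(profile_from_image(flat, c(1, 9), c(9, 9), 1, 0.1),
               "16 samples")
})
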