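# Shared fixture builders. Everything is generated in code; no files.

# Reference striation profiles at the control-like and disease-like
# spacings used throughout the suite.
ctrl_profile <- function(seed = 0, jitter = 0.03, noise = 0.1) {
  make_striation_profile(1.99, 0.1, 40, jitter_sigma = jitter,
                         noise_sigma = noise, seed = seed)
}

ko_profile <- function(seed = 0, jitter = 0.03, noise = 0.1) {
  make_striation_profile(2.70, 0.1, 40, jitter_sigma = jitter,
                         noise_sigma = noise, seed = seed)
}

# Brute-force periodogram oracle: direct cosine/sine projections of the
# Hann-windowed, mean-subtracted profile at each candidate frequency,
# normalized like the FFT path (independent of stats::fft).
periodogram_oracle <- function(profile, freqs) {
  x <- profile$intensity - mean(profile$intensity)
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  xw <- x * w
  pos <- profile$positions_um
  vapply(freqs, function(f) {
    c_ <- sum(xw * cos(2 * pi * f * pos))
    s_ <- sum(xw * sin(2 * pi * f * pos))
    2 * sqrt(c_^2 + s_^2) / sum(w)
  }, numeric(1))
}

# Exhaustive per-pixel neighbor-count classification oracle for skeleton
# pixel classes (double loop; small masks only).
classify_oracle <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  out <- matrix("", nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!skel[r, cc]) next
    nb <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc && skel[rr, c2]) {
        nb <- nb + 1L
      }
    }
    out[r, cc] <- if (nb == 0) "isolated" else if (nb == 1) "endpoint"
                  else if (nb == 2) "slab" else "junction"
  }
  out
}

# Brute-force Holm-Sidak step-down: explicit loop over the sorted
# hypotheses, no vectorized shortcuts.
holm_sidak_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    a <- 1 - (1 - p[o[i]])^(m - i + 1)
    running <- max(running, a)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Expected measured time-to-peak for the half-cosine rise: the analysis
# defines onset at the 10% amplitude crossing, which for
# 0.5 * (1 - cos(pi * s)) sits at s = acos(0.8) / pi of the ramp.
expected_measured_ttp <- function(ttp_true, onset_frac = 0.10) {
  (1 - acos(1 - 2 * onset_frac) / pi) * ttp_true
}
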