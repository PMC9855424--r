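# Synthetic calcium transients with known kinetics.

#' Generate a synthetic calcium transient trace
#'
#' Builds a fluorescence (or ratio) time series of periodic calcium
#' transients with fully known kinetics. Successive beat intervals are
#' `interval_s` plus optional i.i.d. Gaussian jitter (truncated so
#' successive transients never overlap), making `interval_jitter_sd_s`
#' the SD of the realized beat intervals. Each transient rises from the
#' diastolic level to `diastolic + amplitude` over `ttp_s` along a smooth
#' monotone half-cosine ramp (the peak is exactly at onset + `ttp_s`),
#' then decays monoexponentially with time constant `tau_s` toward the
#' diastolic level; each beat's contribution ends at the next onset.
#' Additive Gaussian noise and a linear drift are optional.
#'
#' Defaults mirror a field-stimulation recording: 0.5 Hz pacing
#' (2 s interval) sampled at 50 frames/s.
#'
#' @param duration_s recording length in seconds.
#' @param fs_hz sampling rate (frames per second).
#' @param mode `"paced"` (regular stimulation) or `"spontaneous"`.
#' @param interval_s mean beat interval in seconds; must exceed
#'   `ttp_s + tau_s`.
#' @param interval_jitter_sd_s SD of the beat-interval jitter in seconds.
#' @param ttp_s time to peak (onset to peak) in seconds.
#' @param tau_s monoexponential decay time constant in seconds.
#' @param amplitude transient amplitude (signal units above diastolic).
#' @param diastolic diastolic (baseline) signal level.
#' @param noise_sigma additive Gaussian noise SD.
#' @param drift_per_s linear baseline drift, signal units per second.
#' @param ectopic_prob probability of inserting an extra (ectopic) beat
#'   within each base interval (default 0, off).
#' @param signal_kind one of `"raw"`, `"dff"`, `"ratio"` for the output
#'   trace annotation.
#' @param seed integer RNG seed.
#' @return a `ca_trace` object; ground truth (realized onset and peak
#'   times plus all kinetic parameters) via [synthetic_truth()].
#' @export
make_calcium_trace <- function(duration_s = 30, fs_hz = 50,
                               mode = c("paced", "spontaneous"),
                               interval_s = 2, interval_jitter_sd_s = 0,
                               ttp_s = 0.3, tau_s = 0.4, amplitude = 1,
                               diastolic = 1, noise_sigma = 0,
                               drift_per_s = 0, ectopic_prob = 0,
                               signal_kind = "ratio", seed = 0) {
  mode <- match.arg(mode)
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(fs_hz, "fs_hz", positive = TRUE)
  assert_scalar_num(interval_s, "interval_s", positive = TRUE)
  assert_scalar_num(ttp_s, "ttp_s", positive = TRUE)
  assert_scalar_num(tau_s, "tau_s", positive = TRUE)
  assert_scalar_num(amplitude, "amplitude", positive = TRUE)
  assert_scalar_num(interval_jitter_sd_s, "interval_jitter_sd_s",
                    nonneg = TRUE)
  assert_scalar_num(ectopic_prob, "ectopic_prob", nonneg = TRUE)
  if (ttp_s + tau_s >= interval_s) {
    stop(sprintf(paste("transients would overlap: ttp_s + tau_s = %g",
                       "must be < interval_s = %g"),
                 ttp_s + tau_s, interval_s), call. = FALSE)
  }
  min_gap <- ttp_s + tau_s
  with_seed(seed, {
    n_base <- length(seq(0, duration_s - ttp_s, by = interval_s))
    onsets <- if (interval_jitter_sd_s > 0) {
      # i.i.d. interval jitter: each realized interval is
      # interval_s + eps_k, truncated at the non-overlap floor
      eps <- stats::rnorm(n_base - 1L, 0, interval_jitter_sd_s)
      cumsum(c(0, pmax(interval_s + eps, min_gap + 2 / fs_hz)))
    } else {
      seq(0, duration_s - ttp_s, by = interval_s)
    }
    if (ectopic_prob > 0) {
      extra <- c()
      for (k in seq_len(length(onsets) - 1L)) {
        gap <- onsets[k + 1] - onsets[k]
        if (stats::runif(1) < ectopic_prob && gap > 2 * min_gap) {
          extra <- c(extra, onsets[k] + stats::runif(1, 0.35, 0.65) * gap)
        }
      }
      onsets <- sort(c(onsets, extra))
    }
    onsets <- onsets[onsets < duration_s]
    if (any(diff(onsets) < min_gap)) {
      stop("realized beat intervals too short: transients overlap",
           call. = FALSE)
    }
    n <- as.integer(round(duration_s * fs_hz))
    t <- (seq_len(n) - 1L) / fs_hz
    v <- rep(diastolic, n) + drift_per_s * t
    bounds <- c(onsets[-1], Inf)
    for (k in seq_along(onsets)) {
      o <- onsets[k]; pk <- o + ttp_s
      i_rise <- which(t >= o & t <= pk)
      v[i_rise] <- v[i_rise] +
        amplitude * 0.5 * (1 - cos(pi * (t[i_rise] - o) / ttp_s))
      i_dec <- which(t > pk & t < bounds[k])
      v[i_dec] <- v[i_dec] + amplitude * exp(-(t[i_dec] - pk) / tau_s)
    }
    if (noise_sigma > 0) v <- v + stats::rnorm(n, 0, noise_sigma)
    tr <- ca_trace(t, v, signal_kind = signal_kind)
    peaks <- onsets + ttp_s
    params <- list(duration_s = duration_s, fs_hz = fs_hz, mode = mode,
                   interval_s = interval_s,
                   interval_jitter_sd_s = interval_jitter_sd_s,
                   ttp_s = ttp_s, tau_s = tau_s, amplitude = amplitude,
                   diastolic = diastolic, noise_sigma = noise_sigma,
                   drift_per_s = drift_per_s, ectopic_prob = ectopic_prob)
    truth <- list(onsets_s = onsets, peaks_s = peaks[peaks < duration_s],
                  ttp_s = ttp_s, tau_s = tau_s, amplitude = amplitude,
                  diastolic = diastolic, interval_s = interval_s,
                  interval_jitter_sd_s = interval_jitter_sd_s,
                  rate_hz = 1 / interval_s)
    attr(tr, "synthetic_spec") <-
      synthetic_spec(seed, "calcium_trace", params, truth)
    tr
  })
}

#' Generate a paired Fura-2 340/380 recording from a ratio trace
#'
#' Inverse construction for the ratiometric pipeline: given a known
#' ratio trace \eqn{R(t)}, emits the excitation pair
#' \deqn{F_{380}(t) = background + f380\_baseline + \epsilon,\quad
#'       F_{340}(t) = background + R(t) \cdot f380\_baseline + \epsilon,}
#' so that background-subtracted division recovers \eqn{R(t)} exactly in
#' the noiseless case.
#'
#' @param ratio_trace a strictly positive `ca_trace` (e.g. from
#'   [make_calcium_trace()]).
#' @param f380_baseline 380-nm channel level above background (> 0,
#'   must exceed `background`).
#' @param noise_sigma per-channel additive Gaussian noise SD.
#' @param background additive background common to both channels.
#' @param seed integer RNG seed.
#' @return list with `f340` and `f380` (`ca_trace`, kind `"raw"`) and an
#'   attached `synthetic_spec` recording the input ratio and background.
#' @export
make_fura2_pair <- function(ratio_trace, f380_baseline = 100,
                            noise_sigma = 0, background = 0, seed = 0) {
  stopifnot(inherits(ratio_trace, "ca_trace"))
  assert_scalar_num(f380_baseline, "f380_baseline", positive = TRUE)
  assert_scalar_num(background, "background", nonneg = TRUE)
  if (any(ratio_trace$values <= 0)) {
    stop("`ratio_trace` must be strictly positive", call. = FALSE)
  }
  if (f380_baseline <= background) {
    stop("`f380_baseline` must exceed `background`", call. = FALSE)
  }
  n <- length(ratio_trace$values)
  with_seed(seed, {
    e1 <- if (noise_sigma > 0) stats::rnorm(n, 0, noise_sigma) else rep(0, n)
    e2 <- if (noise_sigma > 0) stats::rnorm(n, 0, noise_sigma) else rep(0, n)
    f340 <- ca_trace(ratio_trace$time_s,
                     background + ratio_trace$values * f380_baseline + e1,
                     signal_kind = "raw")
    f380 <- ca_trace(ratio_trace$time_s,
                     background + f380_baseline + e2,
                     signal_kind = "raw")
    out <- list(f340 = f340, f380 = f380)
    params <- list(f380_baseline = f380_baseline, noise_sigma = noise_sigma,
                   background = background)
    truth <- list(ratio = ratio_trace$values, background = background,
                  upstream = synthetic_truth(ratio_trace))
    attr(out, "synthetic_spec") <-
      synthetic_spec(seed, "fura2_pair", params, truth)
    out
  })
}
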