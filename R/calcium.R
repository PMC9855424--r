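# Calcium-transient analysis: beat detection, per-transient kinetics
# (time to peak, monoexponential decay tau, amplitude, diastolic level)
# and per-cell summary metrics including beat-interval irregularity.

#' Construct a calcium trace
#'
#' @param time_s time stamps in seconds (uniform grid, first frame at
#'   t = 0 by convention; uniformity enforced within 1% relative step
#'   tolerance).
#' @param values signal values (raw fluorescence, dF/F0, or 340/380
#'   ratio); must be finite.
#' @param signal_kind one of `"raw"`, `"dff"`, `"ratio"`.
#' @return a `ca_trace` object with fields `time_s`, `values`,
#'   `signal_kind`, `fs_hz`.
#' @export
ca_trace <- function(time_s, values, signal_kind = c("raw", "dff", "ratio")) {
  signal_kind <- match.arg(signal_kind)
  if (length(time_s) != length(values)) {
    stop("time and value vectors differ in length", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("trace values must be finite",
                                    call. = FALSE)
  dt <- diff(time_s)
  if (length(dt) < 1L || any(dt <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  step <- stats::median(dt)
  if (any(abs(dt - step) > 0.01 * step)) {
    bad <- which(abs(dt - step) > 0.01 * step)[1]
    stop(sprintf("time grid not uniform (first offending step at row %d)",
                 bad + 1L), call. = FALSE)
  }
  fs <- 1 / step
  if (length(values) < 2 * fs) {
    stop("trace must cover at least 2 seconds", call. = FALSE)
  }
  structure(list(time_s = as.numeric(time_s), values = as.numeric(values),
                 signal_kind = signal_kind, fs_hz = fs),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("Calcium trace [%s]: %d samples at %.3g Hz (%.3g s)\n",
              x$signal_kind, length(x$values), x$fs_hz,
              length(x$values) / x$fs_hz))
  invisible(x)
}

#' @export
plot.ca_trace <- function(x, ...) {
  ylab <- switch(x$signal_kind, raw = "F (a.u.)", dff = "dF/F0",
                 ratio = "F340/F380")
  graphics::plot(x$time_s, x$values, type = "l", xlab = "Time (s)",
                 ylab = ylab, ...)
  invisible(x)
}

#' Baseline-normalize a raw fluorescence trace to dF/F0
#'
#' F0 is a low percentile of the trace (default 10th, a robust stand-in
#' for the diastolic level); the output is `(F - F0) / F0`.
#'
#' @param trace a `ca_trace` of kind `"raw"`.
#' @param baseline_percentile percentile (0-100) defining F0.
#' @return a `ca_trace` of kind `"dff"`.
#' @export
compute_dff <- function(trace, baseline_percentile = 10) {
  stopifnot(inherits(trace, "ca_trace"))
  f0 <- unname(stats::quantile(trace$values, baseline_percentile / 100,
                               names = FALSE))
  if (f0 <= 0) {
    stop("baseline F0 <= 0; subtract the camera background first or supply a background-corrected trace",
         call. = FALSE)
  }
  ca_trace(trace$time_s, (trace$values - f0) / f0, signal_kind = "dff")
}

#' Compute a background-corrected 340/380 excitation ratio trace
#'
#' @param f340,f380 `ca_trace` objects on identical time grids.
#' @param bg340,bg380 channel backgrounds subtracted before division.
#' @return a `ca_trace` of kind `"ratio"`.
#' @export
compute_ratio <- function(f340, f380, bg340 = 0, bg380 = 0) {
  stopifnot(inherits(f340, "ca_trace"), inherits(f380, "ca_trace"))
  if (length(f340$time_s) != length(f380$time_s) ||
      any(abs(f340$time_s - f380$time_s) > 1e-9)) {
    stop("340 and 380 traces are not on the same time grid", call. = FALSE)
  }
  den <- f380$values - bg380
  if (any(den <= 0)) {
    stop(sprintf("background-corrected 380 signal <= 0 at sample %d",
                 which(den <= 0)[1]), call. = FALSE)
  }
  ca_trace(f340$time_s, (f340$values - bg340) / den, signal_kind = "ratio")
}

# Strict local maxima of v with plateau handling (plateau midpoint).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) {
        peaks <- c(peaks, (i + j) %/% 2L)
        i <- j + 1L
      } else {
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# Topographic prominence of peak index p in v.
peak_prominence <- function(v, p) {
  n <- length(v)
  left <- if (p > 1L) {
    higher <- which(v[seq_len(p - 1L)] > v[p])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(v[lo:p])
  } else v[p]
  right <- if (p < n) {
    seg <- v[(p + 1L):n]
    higher <- which(seg > v[p])
    hi <- if (length(higher)) p + min(higher) - 1L else n
    min(v[p:hi])
  } else v[p]
  v[p] - max(left, right)
}

#' Detect calcium-transient peaks in a trace
#'
#' Candidate peaks are local maxima of a lightly smoothed copy of the
#' trace (centered moving average, `smooth_s` wide; detection only)
#' whose topographic prominence is at least `min_prominence_frac` of the
#' robust trace range (95th minus 5th percentile), separated by at
#' least `min_interval_s`; when two candidates fall closer the higher
#' one is kept. Each retained candidate is then refined to the raw-trace
#' maximum within the smoothing window, so reported peak times are
#' unsmoothed sample positions (exact on noiseless data).
#'
#' @param trace a `ca_trace`.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   robust range (default 0.3).
#' @param min_interval_s minimum peak separation in seconds
#'   (default 0.25).
#' @param smooth_s width of the detection-only moving average in
#'   seconds (default 0.2; keep well below the beat interval, and
#'   reduce it for beating rates above ~2 Hz).
#' @return numeric vector of peak times in seconds (time order), with
#'   the sample indices in attribute `"index"`. A flat or peak-free
#'   trace yields an empty vector.
#' @export
detect_beats <- function(trace, min_prominence_frac = 0.3,
                         min_interval_s = 0.25, smooth_s = 0.2) {
  stopifnot(inherits(trace, "ca_trace"))
  v <- trace$values
  n <- length(v)
  ks <- max(1L, as.integer(round(smooth_s * trace$fs_hz)) %/% 2L * 2L + 1L)
  hw <- ks %/% 2L
  vs <- if (ks > 1L) {
    # centered moving average with shrinking windows at the edges
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - hw, 1L); hi <- pmin(seq_len(n) + hw, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else v
  rng <- unname(diff(stats::quantile(vs, c(0.05, 0.95), names = FALSE)))
  if (rng <= 0) return(structure(numeric(0), index = integer(0)))
  cand <- local_maxima(vs)
  if (!length(cand)) return(structure(numeric(0), index = integer(0)))
  prom <- vapply(cand, function(p) peak_prominence(vs, p), numeric(1))
  cand <- cand[prom >= min_prominence_frac * rng]
  if (!length(cand)) return(structure(numeric(0), index = integer(0)))
  # enforce separation: keep higher peaks first
  keep <- integer(0)
  for (p in cand[order(vs[cand], decreasing = TRUE)]) {
    if (!length(keep) ||
        all(abs(trace$time_s[p] - trace$time_s[keep]) >= min_interval_s)) {
      keep <- c(keep, p)
    }
  }
  # refine to the raw-trace maximum within the smoothing half-window
  keep <- vapply(keep, function(p) {
    lo <- max(1L, p - hw); hi <- min(n, p + hw)
    lo + which.max(v[lo:hi]) - 1L
  }, integer(1))
  keep <- sort(unique(keep))
  structure(trace$time_s[keep], index = keep)
}

#' Segment a trace into per-beat transient windows
#'
#' For each detected peak, the transient foot (onset) is located as the
#' last upward crossing, before the peak, of
#' `diastolic + onset_frac * (peak - diastolic)`; the diastolic level is
#' the mean of the 100 ms immediately preceding the onset (estimated in
#' two passes: a rough baseline from the pre-peak minimum seeds the
#' crossing search, then the local pre-onset mean refines it). Beat
#' windows are half-open `[onset_k, onset_{k+1})`; the final beat is
#' marked incomplete when its decay is truncated before reaching 1/e of
#' the amplitude. Peaks whose onset cannot be located (e.g. a peak at
#' the start of the trace) are dropped with a message.
#'
#' @param trace a `ca_trace`.
#' @param peaks peak times from [detect_beats()].
#' @param onset_frac onset threshold as a fraction of beat amplitude
#'   (default 0.10, the standard transient-foot convention).
#' @param baseline_window_s width of the pre-onset diastolic window in
#'   seconds (default 0.1).
#' @return a `ca_beats` data frame: `onset_s`, `peak_s`, `ttp_s`,
#'   `amplitude`, `diastolic`, `tau_s`, `fit_r2`, `tau_note`, `complete`,
#'   plus window sample bounds `win_start`, `win_end`.
#' @export
segment_transients <- function(trace, peaks, onset_frac = 0.10,
                               baseline_window_s = 0.1) {
  stopifnot(inherits(trace, "ca_trace"))
  idx <- attr(peaks, "index")
  if (is.null(idx)) {
    idx <- vapply(peaks, function(tp) which.min(abs(trace$time_s - tp)),
                  integer(1))
  }
  if (!length(idx)) return(empty_beats())
  v <- trace$values; tt <- trace$time_s; n <- length(v)
  fs <- trace$fs_hz
  nb <- length(idx)
  rows <- vector("list", nb)
  onset_idx <- rep(NA_integer_, nb)
  for (k in seq_len(nb)) {
    p <- idx[k]
    left <- if (k > 1L) idx[k - 1L] else 1L
    if (p - left < 2L) { message("beat ", k, ": no pre-peak segment; dropped")
                         next }
    seg <- left:p
    find_onset <- function(baseline) {
      thr <- baseline + onset_frac * (v[p] - baseline)
      below <- which(v[seg[-length(seg)]] <= thr &
                       v[seg[-1L]] > thr)
      if (!length(below)) return(NA_integer_)
      seg[max(below)]
    }
    o <- find_onset(min(v[seg]))
    dia <- NA_real_
    if (!is.na(o)) {
      # walk back from the threshold crossing to the transient foot, then
      # average the 100 ms ending at the foot (local diastolic), and
      # re-find the onset with the refined baseline
      foot <- o
      while (foot > left && v[foot - 1L] <= v[foot]) foot <- foot - 1L
      w0 <- max(left, foot - as.integer(round(baseline_window_s * fs)) + 1L)
      dia <- mean(v[w0:foot])
      o2 <- find_onset(dia)
      if (!is.na(o2)) o <- o2
    }
    if (is.na(o)) { message("beat ", k, ": onset not found; dropped"); next }
    rows[[k]] <- data.frame(onset_s = tt[o], peak_s = tt[p],
                            ttp_s = tt[p] - tt[o],
                            amplitude = v[p] - dia, diastolic = dia,
                            tau_s = NA_real_, fit_r2 = NA_real_,
                            tau_note = NA_character_, complete = TRUE,
                            win_start = o, win_end = n,
                            peak_idx = p)
    onset_idx[k] <- o
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(empty_beats())
  beats <- do.call(rbind, rows[keep])
  oi <- onset_idx[keep]
  # half-open windows [onset_k, onset_{k+1})
  if (nrow(beats) > 1L) {
    beats$win_end[-nrow(beats)] <- oi[-1L] - 1L
  }
  # completeness: decay must reach diastolic + amplitude/e inside window
  for (r in seq_len(nrow(beats))) {
    w <- beats$peak_idx[r]:beats$win_end[r]
    thr <- beats$diastolic[r] + beats$amplitude[r] * exp(-1)
    beats$complete[r] <- any(v[w] <= thr)
  }
  class(beats) <- c("ca_beats", "data.frame")
  beats
}

empty_beats <- function() {
  structure(data.frame(onset_s = numeric(0), peak_s = numeric(0),
                       ttp_s = numeric(0), amplitude = numeric(0),
                       diastolic = numeric(0), tau_s = numeric(0),
                       fit_r2 = numeric(0), tau_note = character(0),
                       complete = logical(0), win_start = integer(0),
                       win_end = integer(0), peak_idx = integer(0)),
            class = c("ca_beats", "data.frame"))
}

#' Fit the monoexponential decay of one transient
#'
#' Fits \eqn{y(t) = A e^{-(t - t_{peak})/\tau} + C} by nonlinear least
#' squares on the decay segment from the peak to the earlier of the next
#' onset and the first sample within 5% (of the amplitude) of the
#' diastolic level. Initial values come from a log-linear fit of
#' `y - diastolic`; the fitted offset C absorbs baseline shifts so tau
#' is invariant to constant offsets and robust to slow drift.
#'
#' @param trace a `ca_trace`.
#' @param beat one row of a `ca_beats` frame.
#' @return list with `tau_s`, `fit_r2` and `note` (`NA` note on
#'   success; otherwise a reason code: `"too_few_samples"`,
#'   `"fit_failed"`, `"tau_out_of_range"`).
#' @export
fit_decay_tau <- function(trace, beat) {
  v <- trace$values; tt <- trace$time_s
  p <- beat$peak_idx; e <- beat$win_end
  stop_thr <- beat$diastolic + 0.05 * beat$amplitude
  below <- which(v[p:e] <= stop_thr)
  if (length(below)) e <- p + below[1] - 1L
  if (e - p < 5L) {
    return(list(tau_s = NA_real_, fit_r2 = NA_real_,
                note = "too_few_samples"))
  }
  i <- p:e
  trel <- tt[i] - tt[p]
  y <- v[i]
  win_len <- tt[e] - tt[p]
  z <- y - beat$diastolic
  pos <- z > 0
  if (sum(pos) < 3L) {
    return(list(tau_s = NA_real_, fit_r2 = NA_real_, note = "fit_failed"))
  }
  ll <- stats::lm.fit(cbind(1, trel[pos]), log(z[pos]))
  tau0 <- unname(-1 / ll$coefficients[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- win_len / 3
  a0 <- unname(exp(ll$coefficients[1]))
  if (!is.finite(a0) || a0 <= 0) a0 <- max(z)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-trel / tau) + C,
                      data = data.frame(y = y, trel = trel),
                      start = list(A = a0, tau = tau0, C = beat$diastolic),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(tau_s = NA_real_, fit_r2 = NA_real_, note = "fit_failed"))
  }
  tau <- unname(stats::coef(fit)["tau"])
  if (!is.finite(tau) || tau <= 0 || tau > win_len) {
    return(list(tau_s = NA_real_, fit_r2 = NA_real_,
                note = "tau_out_of_range"))
  }
  res <- stats::resid(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - sum(res^2) / sst)) else NA_real_
  list(tau_s = tau, fit_r2 = r2, note = NA_character_)
}

#' Per-cell summary of calcium-handling metrics
#'
#' Aggregates per-beat features into the per-cell metrics: beating rate
#' (`(n_beats - 1) / (last peak - first peak)`, reported in Hz and bpm),
#' mean time to peak / decay tau / amplitude / diastolic level over
#' complete beats, the standard deviation of successive peak-to-peak
#' intervals (`n - 1` denominator; the beat-interval SD irregularity
#' statistic), and the fraction of intervals deviating more than
#' `irregular_threshold_frac` from the median interval (irregular
#' beating events).
#'
#' @param trace a `ca_trace`.
#' @param beats a `ca_beats` frame (tau fitted or not).
#' @param irregular_threshold_frac relative deviation from the median
#'   interval that classifies an interval as irregular (default 0.25).
#' @return a `trace_summary` list; fields are `NA` where fewer than two
#'   beats make them undefined.
#' @export
summarize_trace <- function(trace, beats, irregular_threshold_frac = 0.25) {
  n_beats <- nrow(beats)
  comp <- beats[beats$complete, , drop = FALSE]
  mean_or_na <- function(x) if (length(x) && any(!is.na(x))) {
    mean(x, na.rm = TRUE)
  } else NA_real_
  out <- list(
    n_beats = n_beats,
    beat_rate_hz = NA_real_, beat_rate_bpm = NA_real_,
    mean_ttp_s = mean_or_na(comp$ttp_s),
    mean_tau_s = mean_or_na(comp$tau_s),
    mean_amplitude = mean_or_na(comp$amplitude),
    mean_diastolic = mean_or_na(comp$diastolic),
    interval_sd_s = NA_real_,
    irregular_event_fraction = NA_real_)
  if (n_beats >= 2L) {
    pk <- beats$peak_s
    # peaks are sample-aligned; snap intervals to the sampling grid so
    # metrically equal intervals are exactly equal despite float rounding
    fs <- trace$fs_hz
    iv <- round(diff(pk) * fs) / fs
    out$beat_rate_hz <- (n_beats - 1L) / sum(iv)
    out$beat_rate_bpm <- 60 * out$beat_rate_hz
    out$interval_sd_s <- if (length(iv) >= 2L) stats::sd(iv) else 0
    med <- stats::median(iv)
    out$irregular_event_fraction <-
      mean(abs(iv - med) > irregular_threshold_frac * med)
  }
  structure(out, class = "trace_summary")
}

#' @export
print.trace_summary <- function(x, ...) {
  cat("Calcium trace summary\n")
  cat(sprintf("  beats: %d   rate: %s Hz (%s bpm)\n", x$n_beats,
              format(x$beat_rate_hz, digits = 4),
              format(x$beat_rate_bpm, digits = 4)))
  cat(sprintf("  TTP: %s s   tau: %s s   amplitude: %s   diastolic: %s\n",
              format(x$mean_ttp_s, digits = 4),
              format(x$mean_tau_s, digits = 4),
              format(x$mean_amplitude, digits = 4),
              format(x$mean_diastolic, digits = 4)))
  cat(sprintf("  interval SD: %s s   irregular events: %s\n",
              format(x$interval_sd_s, digits = 4),
              format(x$irregular_event_fraction, digits = 4)))
  invisible(x)
}

#' @export
as.data.frame.trace_summary <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Full calcium-transient analysis of one trace
#'
#' Convenience wrapper running [detect_beats()], [segment_transients()],
#' [fit_decay_tau()] per beat and [summarize_trace()], returning a
#' classed result with print/summary/plot/coef methods.
#'
#' @param trace a `ca_trace`.
#' @param min_prominence_frac,min_interval_s see [detect_beats()].
#' @param onset_frac see [segment_transients()].
#' @param irregular_threshold_frac see [summarize_trace()].
#' @return a `calcium_analysis` object: list with `trace`, `peaks`,
#'   `beats`, `summary`.
#' @export
analyze_calcium_trace <- function(trace, min_prominence_frac = 0.3,
                                  min_interval_s = 0.25, onset_frac = 0.10,
                                  irregular_threshold_frac = 0.25) {
  peaks <- detect_beats(trace, min_prominence_frac, min_interval_s)
  beats <- segment_transients(trace, peaks, onset_frac = onset_frac)
  for (r in seq_len(nrow(beats))) {
    f <- fit_decay_tau(trace, beats[r, ])
    beats$tau_s[r] <- f$tau_s
    beats$fit_r2[r] <- f$fit_r2
    beats$tau_note[r] <- f$note
  }
  structure(list(trace = trace, peaks = peaks, beats = beats,
                 summary = summarize_trace(trace, beats,
                                           irregular_threshold_frac)),
            class = "calcium_analysis")
}

#' @export
print.calcium_analysis <- function(x, ...) {
  print(x$trace)
  print(x$summary)
  invisible(x)
}

#' @export
summary.calcium_analysis <- function(object, ...) object$summary

#' @export
coef.calcium_analysis <- function(object, ...) {
  s <- object$summary
  c(n_beats = s$n_beats, beat_rate_hz = s$beat_rate_hz,
    beat_rate_bpm = s$beat_rate_bpm, mean_ttp_s = s$mean_ttp_s,
    mean_tau_s = s$mean_tau_s, mean_amplitude = s$mean_amplitude,
    mean_diastolic = s$mean_diastolic, interval_sd_s = s$interval_sd_s,
    irregular_event_fraction = s$irregular_event_fraction)
}

#' @export
plot.calcium_analysis <- function(x, ...) {
  plot(x$trace, ...)
  if (nrow(x$beats)) {
    graphics::points(x$beats$peak_s,
                     x$beats$diastolic + x$beats$amplitude,
                     col = "red", pch = 19, cex = 0.6)
    graphics::points(x$beats$onset_s, x$beats$diastolic,
                     col = "blue", pch = 4, cex = 0.6)
  }
  invisible(x)
}
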