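# Synthetic striation profiles and images with known ground truth.

#' Generate a synthetic sarcomere striation intensity profile
#'
#' Emulates a calibrated 1-D fluorescence intensity signal sampled along a
#' myofibril: a cosine of spatial period `period_um` riding on a baseline,
#' with optional cumulative phase jitter (a per-period random walk that
#' degrades long-range periodicity the way sarcomere disarray does) and
#' additive Gaussian noise.
#'
#' The signal is
#' \deqn{I(x_i) = baseline + amplitude \cos(\phi_i) + \epsilon_i,}
#' where the phase advances by \eqn{2\pi \cdot pixel\_um / period\_um} per
#' sample plus an accumulated Gaussian increment whose standard deviation
#' integrates to `jitter_sigma` radians per period, and
#' \eqn{\epsilon_i \sim N(0, noise\_sigma^2)}.
#'
#' @param period_um striation period in micrometers (> 2 * `pixel_um`).
#' @param pixel_um sampling step in micrometers (must be positive).
#' @param length_um profile length in micrometers (>= 5 periods).
#' @param amplitude,baseline cosine amplitude and additive offset
#'   (arbitrary fluorescence units).
#' @param jitter_sigma cumulative phase jitter, radians per period.
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param seed integer RNG seed; identical (seed, params) reproduce
#'   bit-identical output.
#' @return a `striation_profile` object: list with `positions_um`,
#'   `intensity`, `pixel_um`; ground truth retrievable with
#'   [synthetic_truth()].
#' @seealso [fft_power_spectrum()], [make_striation_image()]
#' @export
make_striation_profile <- function(period_um, pixel_um, length_um,
                                   amplitude = 1, baseline = 0,
                                   jitter_sigma = 0, noise_sigma = 0,
                                   seed = 0) {
  assert_scalar_num(pixel_um, "pixel_um", positive = TRUE)
  assert_scalar_num(period_um, "period_um", positive = TRUE)
  assert_scalar_num(length_um, "length_um", positive = TRUE)
  assert_scalar_num(jitter_sigma, "jitter_sigma", nonneg = TRUE)
  assert_scalar_num(noise_sigma, "noise_sigma", nonneg = TRUE)
  if (period_um <= 2 * pixel_um) {
    stop(sprintf(paste("period_um = %g is at or below the Nyquist limit",
                       "2 * pixel_um = %g; the period is not resolvable"),
                 period_um, 2 * pixel_um), call. = FALSE)
  }
  if (length_um < 5 * period_um) {
    stop("length_um must cover at least 5 periods", call. = FALSE)
  }
  n <- as.integer(round(length_um / pixel_um))
  positions <- (seq_len(n) - 1L) * pixel_um
  step <- 2 * pi * pixel_um / period_um
  with_seed(seed, {
    # phase-jitter random walk: variance accrues jitter_sigma^2 per period
    jit <- if (jitter_sigma > 0) {
      cumsum(stats::rnorm(n, 0, jitter_sigma * sqrt(pixel_um / period_um)))
    } else rep(0, n)
    phase <- (seq_len(n) - 1L) * step + jit
    eps <- if (noise_sigma > 0) stats::rnorm(n, 0, noise_sigma) else rep(0, n)
    intensity <- baseline + amplitude * cos(phase) + eps
    prof <- structure(
      list(positions_um = positions, intensity = intensity,
           pixel_um = pixel_um),
      class = "striation_profile")
    params <- list(period_um = period_um, pixel_um = pixel_um,
                   length_um = length_um, amplitude = amplitude,
                   baseline = baseline, jitter_sigma = jitter_sigma,
                   noise_sigma = noise_sigma)
    truth <- list(period_um = period_um, jitter_sigma = jitter_sigma,
                  noise_sigma = noise_sigma, amplitude = amplitude,
                  baseline = baseline, phase = phase)
    attr(prof, "synthetic_spec") <-
      synthetic_spec(seed, "striation_profile", params, truth)
    prof
  })
}

#' Construct a striation profile from raw vectors
#'
#' @param intensity numeric vector of fluorescence intensities (>= 16 samples).
#' @param pixel_um sampling step in micrometers.
#' @return a `striation_profile` object.
#' @export
striation_profile <- function(intensity, pixel_um) {
  assert_scalar_num(pixel_um, "pixel_um", positive = TRUE)
  if (!is.numeric(intensity) || length(intensity) < 16L ||
      any(!is.finite(intensity))) {
    stop("`intensity` must be a finite numeric vector of >= 16 samples",
         call. = FALSE)
  }
  structure(list(positions_um = (seq_along(intensity) - 1L) * pixel_um,
                 intensity = as.numeric(intensity), pixel_um = pixel_um),
            class = "striation_profile")
}

#' @export
print.striation_profile <- function(x, ...) {
  cat(sprintf("Striation profile: %d samples, %.3g um/px, %.3g um long\n",
              length(x$intensity), x$pixel_um,
              x$pixel_um * length(x$intensity)))
  invisible(x)
}

#' @export
plot.striation_profile <- function(x, ...) {
  graphics::plot(x$positions_um, x$intensity, type = "l",
                 xlab = "Position (um)", ylab = "Intensity (a.u.)", ...)
  invisible(x)
}

#' Generate a 2-D striation image from a profile specification
#'
#' Stacks row-wise phase-jittered copies of a synthetic 1-D striation
#' profile into an image, a stand-in for an alpha-actinin / troponin-T
#' immunofluorescence field with striations perpendicular to a known
#' sampling line. Ground-truth line endpoints for profile extraction are
#' recorded in the attached spec (`truth$line`: `p0`, `p1` in 0-based
#' pixel-center coordinates).
#'
#' @param profile a `striation_profile` from [make_striation_profile()]
#'   (it must carry its synthetic spec; the image re-realizes noise per
#'   row from the stored phase track).
#' @param n_rows number of image rows (>= 1).
#' @param row_jitter_sigma SD of the per-row phase offset (radians).
#' @param orientation_deg rotation of the striation axis; multiples of 90
#'   degrees are supported exactly (0 = striations vary along x).
#' @param seed integer RNG seed.
#' @return numeric matrix (image, `[row, col]`) with a `synthetic_spec`
#'   attribute.
#' @export
make_striation_image <- function(profile, n_rows = 32,
                                 row_jitter_sigma = 0,
                                 orientation_deg = 0, seed = 0) {
  spec <- synthetic_truth(profile)
  if (is.null(spec) || spec$kind != "striation_profile") {
    stop("`profile` must come from make_striation_profile()", call. = FALSE)
  }
  if (!is.numeric(n_rows) || n_rows < 1) stop("n_rows must be >= 1",
                                              call. = FALSE)
  if (orientation_deg %% 90 != 0) {
    stop("orientation_deg must be a multiple of 90 degrees", call. = FALSE)
  }
  n_rows <- as.integer(n_rows)
  phase <- spec$truth$phase
  n <- length(phase)
  p <- spec$params
  img <- with_seed(seed, {
    delta <- if (row_jitter_sigma > 0) {
      stats::rnorm(n_rows, 0, row_jitter_sigma)
    } else rep(0, n_rows)
    rows <- lapply(seq_len(n_rows), function(r) {
      eps <- if (p$noise_sigma > 0) stats::rnorm(n, 0, p$noise_sigma) else 0
      p$baseline + p$amplitude * cos(phase + delta[r]) + eps
    })
    do.call(rbind, rows)
  })
  k <- (as.integer(orientation_deg / 90) %% 4L + 4L) %% 4L
  # truth line: along the striation axis through the image center
  mid <- (n_rows - 1) / 2
  line0 <- list(p0 = c(x = 0, y = mid), p1 = c(x = n - 1, y = mid))
  out <- orient_image(img, k)
  line <- list(p0 = orient_point(line0$p0, k, n_row = n_rows, n_col = n),
               p1 = orient_point(line0$p1, k, n_row = n_rows, n_col = n))
  params <- list(n_rows = n_rows, row_jitter_sigma = row_jitter_sigma,
                 orientation_deg = orientation_deg,
                 profile_params = p)
  truth <- c(spec$truth[c("period_um", "jitter_sigma", "noise_sigma",
                          "amplitude", "baseline")],
             list(line = line, pixel_um = p$pixel_um,
                  base_profile = profile$intensity))
  attr(out, "synthetic_spec") <-
    synthetic_spec(seed, "striation_image", params, truth)
  out
}

# Orthogonal image orientations: 90 is a transpose, 180 a double flip,
# 270 a transpose followed by 180. orient_point maps 0-based pixel-center
# coordinates consistently (n_row/n_col are the ORIGINAL dimensions).
orient_image <- function(img, k) {
  switch(as.character(k),
         "0" = img,
         "1" = t(img),
         "2" = img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img))),
                   drop = FALSE],
         "3" = {
           m <- t(img)
           m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
         })
}

orient_point <- function(pt, k, n_row, n_col) {
  x <- unname(pt["x"]); y <- unname(pt["y"])
  switch(as.character(k),
         "0" = c(x = x, y = y),
         "1" = c(x = y, y = x),
         "2" = c(x = n_col - 1 - x, y = n_row - 1 - y),
         "3" = c(x = n_row - 1 - y, y = n_col - 1 - x))
}
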