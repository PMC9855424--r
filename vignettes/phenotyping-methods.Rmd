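---
title: "Methods: quantitative phenotyping of iPSC-derived cardiomyocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative phenotyping of iPSC-derived cardiomyocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

myoquant implements the quantitative readouts that recur in
cardiomyocyte disease-modeling studies built on human induced
pluripotent stem cell derived cardiomyocytes (iPSC-CMs): sarcomere
organization scored from immunofluorescence striation profiles, calcium
transient kinetics and beat-interval irregularity from fluorescence
traces, skeleton-based mitochondrial morphometry with normalized
reactive-oxygen-species (ROS) readouts, and the small arithmetic of
qPCR and densitometry quantification with multiplicity-adjusted group
comparisons. This vignette describes the models behind each readout,
the tunable parameters and their defaults, the synthetic-data generator
used for validation, and the numerical choices made where the
literature leaves the procedure open.

## Sarcomere organization by Fourier analysis

A striated myofibril stained for a Z-disc or thin-filament marker
(alpha-actinin, troponin T) produces a near-periodic intensity profile
along the fibril axis, with a spatial repeat of about 2 um in healthy
human cardiomyocytes. `fft_power_spectrum()` transforms a calibrated
profile from the length domain into a power distribution over spatial
frequency:

1. subtract the profile mean;
2. apply a Hann window;
3. zero-pad to four times the profile length;
4. take the discrete Fourier transform.

The reported power is **amplitude-normalized**:
$P(f) = 2\,|X(f)| / \sum_i w_i$, where $w$ is the window. With this
normalization a unit-amplitude pure cosine scores a main peak power of
1.0, the score scales linearly with intensity gain, and the coherent
gain of the window cancels. The **main period** is the reciprocal of
the frequency of the largest power bin whose period lies inside the
search band; exact ties break toward the lowest frequency. The **main
peak power** is `regularity_score()`'s raw output: the more phase
disorder (sarcomere disarray) and noise a profile carries, the more
power leaks out of the main peak and the lower the score.

Parameter choices:

* **Search band** 1.0--5.0 um (periods). This brackets the ~2 um
  physiological spacing and the widened pathological spacing while
  excluding pixel-scale noise and profile-scale trends. Configurable
  per call.
* **Hann window + 4x zero-padding.** The window controls spectral
  leakage, which would otherwise let a strong off-bin peak smear into
  neighboring periods; 4x padding refines peak localization to a
  quarter of the natural bin width. For a 40 um profile sampled at
  0.1 um this places the period estimate within ~0.01 um of the truth
  at a 2 um period — an order of magnitude tighter than the ~0.07 um
  spread reported for real cell populations.
* **Raw peak versus band-integrated power.** The regularity index is
  the raw peak power, not an integral over the band; the raw peak is
  what the normalization calibrates, and integration would mix
  period-estimation error into the regularity score.
* **Amplitude normalization option.** `regularity_score(normalize =
  "amplitude")` divides by a robust half-range (the 5th-to-95th
  percentile spread halved), making scores comparable across staining
  intensities; the default raw score is comparable only across
  profiles analyzed with identical settings.
* A constant profile has no periodicity: the spectrum is flagged and
  scores 0 with a warning rather than inventing a peak.

Profiles can come directly from a CSV or be sampled from an image with
`profile_from_image()`, which interpolates bilinearly along a line
(0-based pixel-center coordinates) at one sample per pixel of path
length, averaging an odd number of parallel offset lines.

## Calcium transient analysis

Input traces are uniform-grid time series (`ca_trace`): raw
fluorescence, baseline-normalized dF/F0 (`compute_dff()`, F0 = 10th
percentile by default), or background-corrected Fura-2 340/380
excitation ratios (`compute_ratio()`). The ratiometric path matters
clinically: the ratio's inter-beat baseline is the *diastolic calcium*
level, which single-wavelength dyes cannot report robustly.

The per-trace pipeline is:

* **Beat detection** (`detect_beats()`): local maxima of a lightly
  smoothed copy of the trace (centered moving average, 0.2 s by
  default, used for detection only), kept when their topographic
  prominence exceeds 30% of the robust range (95th minus 5th
  percentile) and they are at least 0.25 s apart; each retained peak is
  then refined to the raw-trace maximum inside the smoothing window,
  so on clean data reported peak times are sample-exact. The smoothing
  width suppresses spurious noise maxima on the flat diastolic
  segments at signal-to-noise ratios down to about 5; for beating
  faster than ~2 Hz it should be reduced.
* **Segmentation** (`segment_transients()`): the transient foot
  (onset) is the last upward crossing, before the peak, of
  `diastolic + 0.10 * (peak - diastolic)` — the standard 10%-foot
  convention that keeps time-to-peak well defined on noisy data. The
  diastolic level is local per beat: the trace is walked back from the
  crossing to the foot and averaged over the 100 ms ending there.
  Per-beat baselines make the metrics robust to slow drift; a
  global-minimum diastolic can be emulated by passing a detrended
  trace. Windows are half-open `[onset_k, onset_{k+1})`; the last beat
  is flagged incomplete if its decay is truncated before reaching 1/e
  of the amplitude, and peaks with no pre-peak samples are dropped.
* **Decay fitting** (`fit_decay_tau()`): a three-parameter
  monoexponential $y(t) = A e^{-(t-t_{peak})/\tau} + C$ fitted by
  Levenberg-Marquardt least squares on the segment from the peak to
  the earlier of the next onset and the first sample within 5% of the
  diastolic level, initialized from a log-linear fit. The free offset
  $C$ makes $\hat\tau$ invariant to constant shifts and tolerant of
  slow drift; fits with fewer than 5 decay samples, nonpositive
  $\tau$, or $\tau$ exceeding the window length are reported as
  missing with a reason code rather than as numbers.
* **Summary** (`summarize_trace()`): beating rate
  `(n_beats - 1) / (last peak - first peak)` in Hz and bpm; means of
  time-to-peak, tau, amplitude and diastolic level over complete
  beats; the **beat-interval SD** (sample SD of successive
  peak-to-peak intervals, the pro-arrhythmic irregularity statistic);
  and the **irregular-event fraction**, the share of intervals
  deviating more than 25% from the median interval. Both irregularity
  metrics are emitted because both appear in practice. Intervals are
  snapped to the sampling grid before differencing so that metrically
  equal intervals are exactly equal in floating point; a paced,
  jitter-free recording therefore reports an interval SD of exactly 0.

A note on reported time-to-peak: because onset is defined at the 10%
foot, the measured rise time on a smooth ramp is the 10%-to-peak time,
i.e. about 80% of the full foot-to-peak duration for the generator's
half-cosine rise. The tests account for this closed form rather than
pretending the two definitions coincide.

## Mitochondrial morphometry and ROS

`segment_mitochondria()` applies a 3x3 median filter then Otsu (or a
fixed) threshold and discards components under 4 px. The median filter
trades single-pixel fidelity (it clips isolated corners) for salt
noise robustness. `skeletonize()` implements Zhang-Suen thinning;
no installed image package provides topological thinning, so it is
implemented here and validated against an exhaustive neighbor-count
oracle. `skeleton_stats()` classifies skeleton pixels by 8-neighbor
count — endpoints (1), slab (2), junctions (3+) — and merges
8-adjacent junction pixels into single junction nodes before branch
counting, preventing 2x2 junction clusters from inflating counts.
Components without junctions are *individuals* (punctate or rod
mitochondria); components with junctions are *networks*; branches are
maximal slab paths between nodes, with diagonal steps counting
sqrt(2). Reported statistics follow the skeleton-network convention:
individuals, networks, mean branches per network, mean and total
branch length, and footprint (mask area). Lengths are in pixels unless
a pixel size is supplied. Thinning shortens a dilated tube by roughly
one pixel per rounded cap, so measured branch lengths sit slightly
below the drawn centerline length; the tests encode that expectation.

ROS quantification is deliberately plain: `mito_ros_ratio()` is the
mean in-mask superoxide-channel intensity divided by the mean in-mask
mitochondrial-mass-channel intensity (gain-invariant when both
channels share the gain), and `cyto_ros_rfu()` is the mean in-mask
cytosolic reporter intensity in relative fluorescent units
(gain-linear), both with optional background subtraction.

## Quantification statistics

`fold_change_ddct()` computes $2^{-\Delta\Delta CT}$ from the four
cycle-threshold values; swapping sample and control exactly inverts
the fold change. `band_ratio()` and `normalize_to_control()` implement
densitometry ratios and the "control mean normalized to 1" convention.
`pairwise_compare()` runs two-sided two-sample t tests per requested
pair — pooled-variance by default, matching the classical post-hoc
convention, with Welch available since published methods often leave
the choice unstated — and adjusts across the family either by the
Holm-Sidak step-down ($p^{adj}_{(i)} = 1 - (1-p_{(i)})^{m-i+1}$,
monotonized) or by Tukey's studentized-range test pooling the
within-group variance across all groups. A full two-way ANOVA
decomposition is intentionally out of scope: every reported contrast
in this assay family is a pairwise comparison with adjustment, and
that decision structure is reproduced without re-deriving unreported
design matrices.

## The synthetic-data generator

No public raw microscopy accompanies studies of this kind, so every
analysis stage is validated by parameter recovery on synthetic
fixtures whose ground truth travels with the artifact (a
`synthetic_spec` attribute: seed, parameters, truth; retrievable with
`synthetic_truth()`, serializable as a YAML sidecar). All generators
are pure functions of their seed and parameters, restore the caller's
RNG state, and default to seed 0.

* **Striation profiles**: a cosine of known period with cumulative
  phase jitter — a random walk accruing a chosen SD (radians) per
  period — plus white noise. The random-walk form is chosen over
  i.i.d. per-pixel jitter because disarray degrades *long-range*
  periodicity, which is what the power spectrum is sensitive to.
  Images stack phase-jittered rows; orientations are restricted to
  multiples of 90 degrees so the ground-truth sampling line stays
  exact rather than interpolation-dependent.
* **Calcium traces**: beats rise from the diastolic level along a
  half-cosine ramp over the time-to-peak (smooth, monotone, peak
  exactly at onset + TTP, making ground-truth TTP unambiguous) and
  decay monoexponentially toward baseline, truncated at the next
  onset; the precondition `ttp + tau < interval` keeps the truncation
  residual under $e^{-1}$ of the amplitude (about 1.4% at the default
  0.5 Hz pacing, 0.3 s TTP, 0.4 s tau). Interval jitter is i.i.d. per
  interval so that the jitter SD parameter *is* the SD of realized
  beat intervals; an optional ectopic-beat probability (off by
  default) inserts extra beats mid-interval. Defaults mirror a
  field-stimulation recording: 0.5 Hz pacing sampled at 50 frames/s.
* **Fura-2 pairs**: the inverse construction
  $F_{380} = b + f$, $F_{340} = b + R(t) f$, so background-subtracted
  division recovers the ratio exactly, and an unsubtracted common
  background provably biases the ratio toward 1.
* **Mitochondrial images**: a segment layout is rasterized, dilated,
  blurred and noised; the truth (individuals, networks, branch counts
  and lengths) is computed analytically from the layout graph, with
  T-junctions splitting the touched segment. Interior-to-interior
  crossings and collinear overlaps are rejected because rasterization
  would merge what the layout keeps distinct, leaving no unambiguous
  truth.
* **ROS pairs**: uniform in-mask channel levels plus noise; the truth
  ratio is the level ratio.

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data: photobleaching beyond
linear drift, dye saturation and buffering kinetics, motion artifacts,
cell segmentation error, spatially correlated (non-white) noise,
out-of-focus light, and 3-D mitochondrial structure projected to 2-D.
Recovery results here certify the *estimators*, not the microscopy.

## Problem sizes and runtime choices

The validation suite favors many small fixtures over few large ones:
40 um profiles at 0.1 um sampling (400 samples), 20-seed replicate
sets for period recovery, 50-seed Monte-Carlo sets for monotonicity
and robustness properties, 30-60 s traces at 25-50 frames/s, toy
skeleton layouts under 40x40 px, and a 2000-replicate null simulation
(5 groups of n = 20, 4 comparisons) for the family-wise error check.
These sizes make every property decisive at desk scale while the full
suite runs in about a minute.

## Known limitations

* The FFT regularity score depends on profile length, window and band;
  absolute values are not comparable across settings, only within.
* Beat detection assumes transients are the dominant structure; it is
  not an arrhythmia classifier, and extreme tachyarrhythmia (beat
  spacing under the smoothing width) requires retuning.
* Skeleton statistics inherit thinning artifacts (cap erosion,
  junction-cluster geometry) of order one pixel or one branch;
  sub-pixel mitochondrial morphology is out of scope.
* The Tukey adjustment assumes the homoscedastic one-way layout of the
  classical procedure; for strongly unequal variances use Welch t
  tests with Holm-Sidak instead.
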