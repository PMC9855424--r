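# myoquant

Quantitative phenotyping of human iPSC-derived cardiomyocytes
(iPSC-CMs), for labs that score disease models the way cardiomyocyte
studies typically do: sarcomere organization from immunofluorescence,
calcium handling from fluorescence traces, mitochondrial network shape
and oxidative stress from live-cell dyes, and the scalar arithmetic of
qPCR and Western-blot quantification.

## What it computes

**Sarcomere organization.** A striation intensity profile $I(x)$
sampled along a myofibril is transformed into an amplitude-normalized
power distribution over spatial frequency (mean subtraction, Hann
window, 4x zero-padded FFT, $P(f) = 2|X(f)|/\sum_i w_i$). The main
spectral peak inside a 1-5 um period band gives the **striation
period** (~2 um in healthy cells; widened and weakened in disarrayed
sarcomeres) and its height is the **regularity score** (1.0 for a
unit-amplitude pure cosine).

**Calcium transients.** From dF/F0 or ratiometric Fura-2 340/380
traces: beat detection by prominence on a lightly smoothed copy of the
trace, per-beat onset at the 10% amplitude foot, time to peak,
transient amplitude, per-beat diastolic level, monoexponential decay
constant ($y = A e^{-(t - t_{peak})/\tau} + C$, Levenberg-Marquardt),
beating rate, the beat-interval SD (the pro-arrhythmic irregularity
statistic) and the fraction of intervals deviating >25% from the
median.

**Mitochondria and ROS.** Otsu segmentation, Zhang-Suen thinning, and
skeleton-network statistics (individuals, networks, branches per
network, branch lengths, footprint); MitoSOX/MitoTracker mean-intensity
ratio and CellROX mean RFU.

**Quantification statistics.** $2^{-\Delta\Delta CT}$ fold changes,
band-intensity ratios with control-mean normalization, and pairwise
two-sample t tests (pooled or Welch) with Holm-Sidak or Tukey
multiplicity adjustment.

**Synthetic data.** Every analysis has a matching deterministic
generator (`make_striation_profile()`, `make_calcium_trace()`,
`make_fura2_pair()`, `make_mito_image()`, `make_ros_pair()`, ...)
whose ground truth travels with the artifact, so the whole pipeline is
validated by parameter recovery — no external data needed.

## Worked example

```r
library(myoquant)

## sarcomere spacing, healthy-like vs disease-like synthetic profiles
p_ctrl <- make_striation_profile(period_um = 1.99, pixel_um = 0.1,
                                 length_um = 40, jitter_sigma = 0.03,
                                 noise_sigma = 0.1, seed = 1)
fft_power_spectrum(p_ctrl, search_band_um = c(1, 5))
#> Striation spectrum: main period 2.000 um, peak power 0.989 (band 1-5 um, 400 samples)

p_ko <- make_striation_profile(period_um = 2.70, pixel_um = 0.1,
                               length_um = 40, jitter_sigma = 0.03,
                               noise_sigma = 0.1, seed = 1)
fft_power_spectrum(p_ko, search_band_um = c(1, 5))
#> Striation spectrum: main period 2.712 um, peak power 0.990 (band 1-5 um, 400 samples)

## ratiometric calcium recording paced at 0.5 Hz
trace <- make_calcium_trace(duration_s = 60, fs_hz = 50, interval_s = 2,
                            seed = 1)
pair  <- make_fura2_pair(trace, f380_baseline = 100, seed = 1)
ratio <- compute_ratio(pair$f340, pair$f380)
analyze_calcium_trace(ratio)
#> Calcium trace [ratio]: 3000 samples at 50 Hz (60 s)
#> Calcium trace summary
#>   beats: 30   rate: 0.5 Hz (30 bpm)
#>   TTP: 0.24 s   tau: 0.4 s   amplitude: 0.9875   diastolic: 1.013
#>   interval SD: 0 s   irregular events: 0

## qPCR fold change: CTs (target/ref, sample vs control)
fold_change_ddct(20, 18, 22, 18)
#> [1] 4
```

The spectrum recovers each generator's spacing to within one
zero-padded frequency bin (2.000 and 2.712 um here), the paced trace
yields exactly 0.5 Hz with zero interval SD, the measured rise time
(0.24 s) is the 10%-foot-to-peak time of the 0.3 s half-cosine ramp,
and the decay constant matches the generator's 0.4 s.

A command-line wrapper is installed at
`system.file("cli", "myoquant.R", package = "myoquant")` with
subcommands `simulate`, `sarcomere`, `calcium`, `mito`, `ros`,
`stats` and `ddct`.

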