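---
title: "Quantifying neurovascular coupling from aEEG and SctO2 with wavelet coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurovascular coupling from aEEG and SctO2 with wavelet coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcwave)
```

## The problem

In newborns with hypoxic-ischemic encephalopathy, two bedside signals are
monitored for many hours: EEG, summarized clinically as the
amplitude-integrated EEG (aEEG), and cerebral tissue oxygen saturation
(SctO2) from near-infrared spectroscopy. Neurovascular coupling (NVC) —
the co-variation of neuronal activity and cerebral hemodynamics — shows up
as shared slow oscillations (periods of roughly ten minutes to three
hours) between the aEEG bandwidth and SctO2. Because commercial monitors
convert raw EEG to aEEG with different, often undisclosed, algorithms, any
NVC metric built on aEEG must be robust to the choice of conversion. This
package implements the full chain — aEEG conversion by two fully specified
algorithms plus ingestion of device-computed aEEG, wavelet transform
coherence (WTC) against SctO2, surrogate-based significance, pixel
counting, and cross-method agreement statistics — together with a
synthetic-recording generator that provides ground truth for every stage.

## aEEG conversion

All conversions share a preprocessing front end:

1. **Asymmetric band-pass filter.** A linear-phase FIR passing 2–15 Hz
   whose in-band gain *rises* at 12 dB/decade (gain 1 at 2 Hz,
   about +10.5 dB at 15 Hz), compensating scalp and skull attenuation of
   faster activity while strongly rejecting slow artifact (respiration,
   movement) and mains/muscle noise above the band.
2. **Full-wave rectification** (absolute value).
3. **Envelope detection.** A 5th-order low-pass Butterworth applied
   forward–backward (zero phase), clipped at zero.

The two raw-EEG algorithms then differ in gain and segmentation:

* **M1** applies a gain of 2, slides a 15-s window in steps of
  4.78125 s (= 1224 samples at 256 Hz; windows overlap by 10.22 s), takes
  the 90th/10th percentile of each window as upper/lower terminal points,
  and smooths the terminal-point sequences (default: centered 3-point
  moving average) into the upper and lower margin amplitudes (UMA, LMA).
* **M2** applies a gain of 1.631, segments the record into contiguous
  non-overlapping 1224-sample epochs, takes the same percentiles, and
  smooths with a centered 3-point moving average (about 15 s of effective
  support).
* **M3** ingests a 256 Hz aEEG amplitude series computed externally by a
  monitoring device, and applies the same segmentation and margin steps as
  M1. The device's own raw-EEG conversion is not reimplemented; for
  synthetic end-to-end runs the package supplies
  `synthetic_device_aeeg()`, a deliberately different but plausible
  stand-in (symmetric Butterworth band-pass, rectification, envelope,
  gain 2), clearly labelled synthetic.

The margin stride is fixed at 1224 samples so the margin rate is exactly
256/1224 = 0.20915 Hz; "4.78 s" and "0.209 Hz" are the rounded forms of
the same choice, and the SctO2 generator uses the exact value so the two
series share a common rate without resampling. The WTC input is the
**bandwidth** series, UMA − LMA.

Design notes on points the algorithm descriptions leave open:

* The envelope cutoff is not standardized; the default is 1 Hz, far above
  the 0.1–1.6 mHz analysis band and low enough to remove rectification
  ripple. It is configurable.
* Percentiles use linear interpolation between order statistics
  (`stats::quantile` type 7); an independent sort-and-interpolate oracle
  in the test suite pins the convention.
* "A curve drawn through the peaks and troughs" is not an operational
  definition; the default margin smoother is a centered 3-point moving
  average, with a cubic-spline alternative behind a configuration switch.
  Both are recorded in output metadata.
* The nominal segmentation of a 15-s set into "three 4.78-s epochs" is
  arithmetically inconsistent (3 × 4.78125 = 14.34 s); M2 therefore uses
  contiguous 1224-sample epochs over the whole record, which is what the
  stated 0.209 Hz output rate implies.
* The filter is realized by frequency-sampling design
  (`signal::fir2`, Hamming window, 401 taps) rather than an equiripple
  design: the equiripple (Parks–McClellan) routine available to the
  package is numerically unreliable for this narrow-transition,
  shaped-band specification, while the frequency-sampling design is
  robust and matches the desired response to within a few percent
  mid-band. The desired ramp is extended slightly beyond the 2/15 Hz
  corners so window droop falls outside the nominal band; the realized
  2→15 Hz gain ratio is within 0.15 dB of the nominal 10.5 dB.
* Zero-phase filtering uses odd-reflection padding at the record ends to
  suppress start-up transients; the first and last window of margin
  samples remain edge-flagged in metadata, and the coherence stage's cone
  of influence handles boundaries uniformly.

## Wavelet transform coherence

Both the bandwidth and SctO2 series are mean-removed and
variance-normalized, then transformed with the analytic Morlet wavelet
(center frequency 6, the standard choice, Fourier factor about 1.033)
on a dyadic grid of 12 voices per octave. The default grid spans
640–10240 s — the band in which slow NVC oscillations are quantified,
0.1–1.6 mHz under the reciprocal scale-frequency conversion used for axis
labels. Squared coherence is

R²(s, t) = |S(Wxy/s)|² / ( S(|Wx|²/s) · S(|Wy|²/s) ),

where S smooths across scales (boxcar spanning about 0.6 octave) and in
time (Gaussian with SD = scale/√2). Values are clamped to [0, 1];
self-coherence is 1 within numerical error inside the usable region.

**Cone of influence.** Cells within √2 × scale of either record edge are
edge-affected and excluded from all pixel counting. A scale is usable only
if the record is longer than 2√2 × scale, so resolving the full
640–10240 s band requires at least about 8.05 h of common record.

**Significance.** The null model is a pair of independent AR(1) ("red
noise") series whose lag-1 coefficients are estimated from the data. For
each scale, the threshold is the 95th percentile of null coherence pooled
over 300 surrogate pairs and all outside-COI times (accumulated in 2000
bins, resolution 5 × 10⁻⁴). Because this threshold depends only on the
record length, the grid and the two AR(1) coefficients, `wtc_thresholds()`
exposes it as a reusable object: a subject run computes it once and shares
it across the three methods (which are mandated to use an identical grid
and whose bandwidth series have near-identical AR(1) structure). The
Monte-Carlo quantile is evaluated on every second scale and interpolated
linearly in log2(scale); the null quantile varies smoothly across scale,
and the type-I calibration test verifies the end-to-end error rate.
Thresholding is pointwise (no area-wise correction), matching the p < 0.05
contour convention of the underlying method.

**Pixel counting.** One pixel is one (time-sample × scale-bin) cell on the
0.209 Hz × 12-voice grid. `pix_total()` counts significant pixels outside
the COI; the count is grid-dependent, so comparisons across methods are
only meaningful on a shared grid (the pipeline enforces this). The
cross-method variability metric is the coefficient of variation,
COV = 100 × SD/mean of the three methods' Pix_total. The COV could in
principle be computed per scale and then averaged; this implementation
computes it from the three totals, which matches its role as a single
per-subject variability number, and the per-scale alternative is
deliberately not offered.

## Synthetic recordings

`generate_recording()` emulates the measurement conditions the pipeline
targets: 256 Hz EEG for 20 h (default) and SctO2 at 256/1224 Hz. The EEG
is a broadband carrier — white noise for a continuous background, or a
burst-suppression process (seeded Poisson bursts, default 6/min of 2 s,
suppression ratio 0.1) for a discontinuous one — multiplied by a slow
envelope `base × (1 + mod_depth · m(t))`, plus sensor noise. The
modulation m(t) is a sum of seeded-phase sinusoids at the configured
coupling periods, normalized to [−1, 1]. SctO2 receives
`coupling_strength × scto2_coupling_amp_pct × m(t − lag)` around its mean
plus independent AR(1) noise, and is clipped to [0, 100] with clip events
counted. Multiplicative modulation is used precisely so that the aEEG
margins inherit m(t) — the aEEG is an amplitude envelope. The modulation
enters SctO2 with a configurable lag (default 0); coherence magnitude at
fixed scale is phase-insensitive, and no phase analysis is offered.

Default amplitudes (envelope base 25 µV, sensor noise 2 µV SD, SctO2 mean
75%, coupling amplitude 3%, AR(1) noise 1.5% SD with lag-1 coefficient
0.8) are chosen for physiological plausibility on the conventional
0–100 µV semi-log display and for SctO2 values typical of neonatal NIRS;
no quantitative amplitude distributions were available to match, so these
are display-plausible conventions, not fitted values.

What the generator does *not* emulate: real hemodynamic transfer
functions, seizures, artifacts other than stationary noise, multichannel
montages, or nonstationary coupling. Passing tests therefore demonstrate
the correctness and internal calibration of the pipeline, not the
physiology of any real cohort.

## Problem sizes and numerical choices

The validation suite uses these sizes, chosen as the smallest that
exercise each property cleanly:

* Type-I calibration: uncoupled AR(1) pairs (lag-1 coefficient 0.8) of
  length 15000 at 0.20915 Hz (about 20 h), 300 surrogates, 20 replicate
  maps; the outside-COI significant fraction must sit within 3 Monte-Carlo
  standard errors of the nominal 5%.
* Coupling recovery: single 3000-s oscillation at strength 0.8 in a 9-h
  recording; every method must show a contiguous band of scales (each
  with significant fraction ≥ 5× the nominal level) containing 3000 s,
  and a strength-0 twin must show none.
* Cohort robustness: eight 9-h subjects with coupling strengths 0.1–1.0,
  alternating continuous and burst-suppression backgrounds. Nine hours is
  the smallest duration that resolves the full 640–10240 s band outside
  the cone of influence. Pairwise Bland–Altman differences of Pix_total
  must fall within the ±1.96 SD limits, and the per-method regression of
  COV on Pix_total must slope downward (stronger coupling, lower
  cross-method variability).

Other numerical conventions: FFTs are zero-padded to the next power of
two (the COI absorbs wrap-around at the record ends, and time-smoothing
pads far enough that the largest Gaussian cannot wrap); degenerate inputs
(constant series, zero-variance regressors, mean-zero pixel counts) are
rejected or mapped to explicit NA markers rather than silently producing
numbers; agreement statistics use the sample (n−1) SD throughout, which
is material for eight-subject cohorts — and where a methods text says
"one standard deviation" while the corresponding figure specifies ±1.96
SD, the 1.96 convention is implemented with the multiplier configurable.

## Known limitations

* The AR(1) null is an approximation to the spectral structure of real
  bandwidth series; heavy additional smoothing in the margin pipeline
  makes the series redder than AR(1) at short lags. The full-pipeline
  null-calibration test bounds the practical effect.
* When one input is nearly a pure tone — e.g. a strongly modulated aEEG
  bandwidth whose partner signal carries no coupling at all — the
  AR(1)-pair null underestimates the coherence such a narrowband series
  attains against independent noise, and transient exceedances at the
  tone's scale become common (roughly 40% of times in the synthetic null
  experiments) even though nothing is coupled. This is a known weakness
  of pointwise red-noise surrogate tests, not of this implementation.
  The validation suite therefore distinguishes coupling from this
  artifact by *persistence*: a detected band must be significant over at
  least 75% of its usable record, which genuinely coupled synthetic
  subjects satisfy with margin (the injected modulation is always on,
  giving sustained fractions near 1) while the narrowband artifact does
  not. Interpret isolated, non-sustained significance with caution in
  real data.
* Pix_total depends on record length and grid; it is comparable across
  methods and subjects only at fixed geometry.
* The EDF reader/writer covers the plain 16-bit subset used here, not
  EDF+ annotations.
* No artifact rejection beyond the band-pass filter, and no clinical
  background-pattern classification, are provided.
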