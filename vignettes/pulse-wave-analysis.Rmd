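---
title: "Methods: continuous PPG pulse-wave analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous PPG pulse-wave analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

This vignette documents the models, algorithms and numerical choices behind
`pulsewave`: how the signal is conditioned, how beats and fiducial points are
found, how the 74 biomarkers are defined, what the synthetic generator does
and does not emulate, and where the design was genuinely open.

## Signal model and preprocessing

A PPG recording is treated as a single uniformly sampled channel. The
analysis needs the signal and its first three derivatives, because most
fiducial points are extrema or zero-crossings of those derivatives, and
derivative estimation amplifies high-frequency noise. The preprocessing chain
is therefore:

1. **Band-pass, 0.5–12 Hz, zero phase.** A Chebyshev Type II design (order 4,
   20 dB stop-band attenuation) applied forward and backward, so the squared
   magnitude response acts with zero phase — fiducial timing must not be
   biased by filter delay. The 0.5 Hz edge removes baseline wander while
   retaining content at heart rates down to 30 bpm; the 12 Hz edge removes
   noise that would create spurious derivative extrema, while cutting low
   enough not to time-shift the pulse onset and dicrotic notch.
   *Numerical note:* at sampling rates near 1 kHz the jointly designed
   band-pass transfer function is unstable in double precision (the lower
   edge sits at ~10^-3 of Nyquist and coefficient rounding pushes poles
   outside the unit circle), so the filter is realized as a cascade of a
   high-pass and a low-pass section of the stated order, which is stable at
   all rates tested (75 Hz–2 kHz). The input mean is subtracted before
   filtering, and the signal is padded by odd reflection over three seconds
   (the slowest pole's decay is ~1 s) so edge transients do not reach the
   interior. The first and last second are still flagged as warm-up and
   excluded from fiducial search.
2. **50 ms moving average (MAF)** on the signal (~9 Hz cut-off), a flat
   boxcar whose window is rounded to samples and forced odd so the kernel
   stays centered (zero phase). At the edges the window shrinks.
3. **Derivatives** by first-order central differences scaled to per-second
   units, with a **10 ms MAF** (~45 Hz cut-off) after every differentiation
   stage. Central differences preserve extremum locations, which the fiducial
   definitions depend on.
4. **75 Hz resampled copy** (Fourier method: spectrum truncation/padding) for
   the beat detector only — beat detection does not need full bandwidth, and
   the lower rate cuts its cost; all other detection runs at the native rate.

All cut-offs, orders, MAF widths and the resample rate are configurable
(`filter_config()`); the defaults above are tuned for fingertip
transmission-mode PPG.

## Beat detection

Systolic peaks are detected on the 75 Hz copy in 10 s windows:

* **Window heart rate.** The candidate rate is the dominant frequency of the
  Hann-windowed periodogram searched over 0.3–5 Hz — deliberately wider than
  the admissible 30–200 bpm, so an out-of-range rhythm is identified at its
  true frequency and *rejected* (the previous window's rate, or the range
  midpoint at the start, is retained and the window marked invalid) rather
  than aliased into the band by pre-filtering.
* **Peak band.** The window is filtered with a zero-phase Chebyshev II
  band-pass (order 5) from 0.5 Hz to `2.5 × HR/60` Hz — wide enough to keep
  the pulse's first harmonics, narrow enough to suppress the dicrotic wave.
* **Candidates and threshold.** Local maxima above the window's 0.7 amplitude
  quantile, pruned strongest-first with a refractory period of 0.6 of the
  HR-implied beat period. The rank threshold adapts to amplitude drift; the
  refractory factor below 1 tolerates HR underestimation without dropping
  true beats.
* **Stitching and refinement.** Each window is processed with one second of
  context on both sides; duplicates within 100 ms at joins keep the
  higher-amplitude peak. Indices are then mapped to the native rate and
  refined to the local maximum of the filtered PPG within ±100 ms. A global
  refractory of `60/hr_max` s is enforced last.

The detector is deterministic: identical input and configuration give
identical output.

## Segmentation and fiducial points

The pulse onset is defined operationally as the first local maximum of the
third derivative preceding the pulse's *p1* point — the beginning of the
systolic upslope, which is usually but not necessarily a minimum. Because
*p1* is itself defined within a pulse, segmentation is two-pass: a
provisional window (PPG minimum before the peak, up to the next peak) places
provisional *a*, *b* and *p1* points, the onset is then refined backward from
*p1*, and all fiducials are recomputed on the final window. The offset of
each pulse is the onset of the next, so retained pulses tile the record. The
final beat's offset is sought near the expected next onset (one median beat
period after the current onset) and refined the same way; if no admissible
point exists the beat is dropped.

Within a pulse `[on, off]` of duration `T`:

| point | rule |
|---|---|
| `u` / `v` / `w` | PPG′ max in `(on, sp]` / min in `(u, e]` / first max in `(max(v, e), f]` |
| `a` / `b` | PPG″ max in `[on, sp]` / first min after `a` |
| `e` / `f` | highest PPG″ max in `(b, on + 0.6T]` / first min after `e` within `on + 0.8T` |
| `c` / `d` | highest max / lowest min strictly inside `(b, e)`; fallback: interior PPG‴ zero-crossing |
| `p1` / `p2` | first PPG‴ max after `b` / last PPG‴ min in `(b, d)`, falling back to `d` |
| `dn` / `dp` | see below |

**Dicrotic notch.** When a diastolic wave is present the notch is the local
PPG minimum preceding the first prominent local maximum after the systolic
peak (class 1, or class 2 when both slope and curvature are near zero there —
a plateau). When no such maximum exists, the notch is the zero-crossing of
PPG″ between the `d` and `e` points (class 3, a gradient change on the
downslope); if that also fails the notch is absent (class 4, typical of
elderly-type waveforms without a discernible notch). The diastolic peak is
the first prominent local maximum after the notch (or after `e` when the
notch route failed), bounded by 0.8 of the pulse interval.

**Numerical guards.** Three guards keep the detectors off numerically
insignificant structure: (i) inflection fallbacks for `c`/`d` exclude a 2%
band around the bracketing extrema, where the next-higher derivative is
trivially zero; (ii) a candidate `f` must be followed by a rise of at least
2% of the pulse's second-derivative range (filter ripple in flat diastolic
tails otherwise mimics the post-`e` trough); (iii) the notch/diastolic-peak
rebound must exceed 2% of the pulse amplitude range. Local extrema are strict
(greater than both neighbours); plateaus count once at their first sample;
zero-crossings are reported at the nearer bracketing sample by linear
interpolation. Degenerate inputs (flat pulses) yield no derivative points
rather than arbitrary ones.

**Correction pass (optional, on by default).** Ordering invariants
(`on ≤ u ≤ sp ≤ dn ≤ dp ≤ off`, `a < b ≤ e < f`, `c`, `d` inside `(b, e)`)
are enforced by discarding inconsistent points; a diastolic peak found at or
before the notch is recomputed from the corrected notch and discarded if
still inconsistent. Points are never moved to satisfy an invariant — a
fabricated fiducial is worse than an absent one. The pass is idempotent and
can be disabled, in which case raw detections pass through unchanged.

**Validity flags.** Pulses whose systolic (onset→notch) or diastolic
(notch→offset) durations fall below 120 ms / 300 ms are flagged invalid.
These floors assume resting adult physiology; at very high rates (>150 bpm)
the diastolic floor fails naturally, so the flags mark pulses rather than
deleting them and the biomarker stage can be told to keep them. The flag is
finalized in the fiducial stage because it needs the notch.

## Biomarkers

The 74 biomarkers fall into four groups — PPG Signal (17), Signal Ratios
(12), PPG Derivatives (15) and Derivatives Ratios (30). Conventions:

* Timings are milliseconds from the pulse onset. Amplitudes of PPG fiducials
  are relative to the onset amplitude; derivative amplitudes (`A_u`, …,
  `A_p2`) are the raw derivative values at the point's sample, in per-second
  units. Areas are trapezoidal integrals of the onset-referenced pulse in
  amplitude·ms.
* Widths at x% (default x = 50, configurable) threshold at
  `PPG(on) + x% · A_sp`, with sub-sample crossings by linear interpolation;
  `Tpwx = Tswx + Tdwx` by construction.
* The reflection indices of `p1`/`p2` use the PPG amplitude at the point
  minus the amplitude at the pulse onset as denominator. The spring constant
  uses PPG″ at the systolic peak in derivative units (documented rather than
  normalized).
* A biomarker whose required fiducials are absent, or whose denominator is
  zero, is absent (`NA`) — never zero.

Summary statistics per biomarker over a window of beats: mean, median, SD
(n−1), quartiles by linear interpolation of the empirical CDF (R type 7),
IQR, adjusted Fisher–Pearson skewness, excess kurtosis, and the mean absolute
deviation from the mean. Zero-variance columns report skewness = kurtosis =
0; all-absent biomarkers are omitted from the summary.

## Signal-quality index

Each pulse is linearly resampled to 100 samples; the template is the
pointwise mean beat; a pulse's quality is its Pearson correlation with the
template, clipped below at zero. The index is invariant to amplitude scaling
and baseline offset, lives in [0, 1], and gates nothing — it is written out
for the user to filter on. This is a deliberately simple template-matching
formulation with the standard 0–1 contract, not a port of any particular
published implementation.

## Validation machinery

* **Beat matching.** A constant lag (searched by cross-correlating the event
  trains binarized at 10 ms, up to `max_lag_ms`) aligns detected to reference
  events; matching is then greedy one-to-one by nearest absolute difference
  (ties to the earlier reference event) within a tolerance (default 150 ms).
  Sensitivity, PPV and their harmonic mean F1 are reported in percent. F1 is
  invariant to constant shifts the lag search covers, and non-decreasing in
  the tolerance.
* **Fiducial errors.** Per point, over pulses where detection and annotation
  both exist: MAE, SD of absolute errors, signed bias, and Bland–Altman
  limits of agreement at bias ± 1.96 SD of the signed differences.

## The synthetic generator

Each beat is a sum of Gaussian waves on the beat period: a systolic wave
(amplitude 1, centre 0.30, width 0.10 of the period), a diastolic wave
(0.35, 0.62, 0.12) and an optional late-systolic reflection wave (off by
default). Beats are concatenated (optionally with per-beat period jitter),
and a baseline sinusoid plus white noise at a stated SNR can be added. The
defaults describe a resting adult fingertip waveform with a moderate
diastolic wave; the widths as period fractions make the morphology
rate-invariant.

Gaussians are used because all derivatives exist in closed form, so every
fiducial point of the noise-free continuous model can be located exactly by
bracketed root-finding and serves as an independent ground truth for the
discrete detectors. The ground truth applies the *same operational
definitions* as the detector, but on the continuous model — it therefore
measures the error introduced by sampling, filtering and discrete extremum
search, which is the quantity of interest. One consequence is worth
flagging: on this smooth morphology the third-derivative onset definition
sits systematically ~0.1 s after the waveform foot (the PPG minimum), so the
foot is reported separately (`foot` column) and onset accuracy is assessed
against the operational definition, not the foot.

The reflection wave exists because two Gaussians cannot produce the
`c`–`d` substructure of the second derivative: those waves arise from a
distinct late-systolic reflection component. The test grid therefore
includes two reflection-wave cells so that `c`, `d` and `p2` are exercised
with known truth.

What the generator does **not** emulate: motion artifacts, sensor-contact
changes, arrhythmia, respiratory amplitude modulation, skin-perfusion
effects, or device transfer characteristics. Passing the synthetic checks
shows the detectors implement their definitions accurately under sampling,
filtering and additive noise — it does not certify performance on ambulatory
or low-perfusion recordings.

## Problem sizes and test design

The suite and the acceptance script use desk-scale problems chosen to
exercise every code path: a morphology grid of eleven cells (systolic width
0.05–0.15 of the period × diastolic amplitude 0–0.6, plus the two
reflection cells) of 20 s at 500 Hz for fiducial accuracy; 60 s recordings at
256 Hz across 40–180 bpm, clean and at 20 dB SNR, for beat detection; 10 s
pulses at 1 kHz for the brute-force definition-equivalence check. Beat
scoring is restricted to the span covered by ground-truth annotations (the
final generated beat has no offset and is reported only partially).

## Known limitations

* The notch detector's class assignment depends on fixed 2%/5% prominence
  and flatness thresholds; borderline incisura/plateau morphologies can land
  in either class (timing is unaffected).
* Onset placement inherits the smoothness of the third derivative: on very
  broad, merged waveforms (systolic width ≥0.15 of the period with a large
  merged diastolic wave) landmark shifts of 15–25 ms were observed — the
  morphology itself carries little curvature to anchor on.
* The EDF and MAT readers cover the common single-channel cases (standard
  EDF; Level-4 MAT with one numeric vector plus an `fs` scalar), not the full
  formats.
* Heart rates outside 30–200 bpm are treated as artifact by design.
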