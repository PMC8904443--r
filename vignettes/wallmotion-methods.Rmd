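---
title: "Temporospatial wall-motion indices: model, phantom and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporospatial wall-motion indices: model, phantom and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallmotion)
```

## The measurement problem

Ungated, free-breathing (real-time) cardiac MRI delivers a continuous
short-axis image series spanning several sequential heartbeats — typically
7–16 cycles at 18–30 ms temporal resolution in a ~7 s window — instead of
the single virtual cycle of ECG-gated, breath-held cine. Every voxel then
carries a complex-valued time series in which local wall motion appears as
a pseudo-periodic intensity fluctuation. `wallmotion` quantifies two
aspects of that fluctuation per ventricle:

* **Temporal periodicity** — how regular the beat-to-beat motion is.
* **Spatial coherence** — how widely the motion spreads over the
  ventricular anatomy.

Both are computed from the image series plus binary endocardial
segmentations of the LV and RV at one end-diastolic (ED) and one
end-systolic (ES) frame. Segmentation itself, image reconstruction and
pulse sequences are out of scope: masks and complex images are inputs.

## The model

**ROI and reference signal.** For each chamber the ROI is the literal set
difference `ED & !ES`: the annular band the endocardial border sweeps
during contraction. The complex series is averaged over the ROI frame by
frame, giving the reference wall-motion signal. Because free breathing
modulates the whole image slowly (~0.2–0.4 Hz) while cardiac motion lives
above ~0.7 Hz at rest, the reference is high-pass filtered before any
spectral or correlation analysis.

**Temporal periodicity.** With `S(f)` the discrete Fourier transform of
the filtered reference (unitary normalization, so spectral energy equals
time-domain energy), the cardiac frequency `f_c` is the in-band peak of
the paired power `|S(+f)|^2 + |S(-f)|^2`, and

```
periodicity = sqrt(|S(f_c)|^2 + |S(-f_c)|^2) /
              sqrt(sum_n |S(f_n)|^2 + |S(-f_n)|^2)
```

Complex image data make the spectrum non-conjugate-symmetric, which is why
positive and negative frequencies enter separately. The value lies in
[0, 1] (Cauchy–Schwarz) and is invariant to global scaling and phase
rotation. Note that the index penalizes *all* off-peak energy, including
harmonics of a perfectly periodic but non-sinusoidal waveform — so even a
noiseless, jitter-free heart does not score 1 unless its wall motion is
sinusoidal.

**Spatial coherence.** The ventricular anatomy VA is the union of the LV
and RV ED masks (`M` voxels). Every VA voxel's series is high-pass
filtered with the same cutoff as the reference, then correlated with the
reference using a Pearson coefficient on complex samples
(mean-subtracted cross-covariance over the product of standard
deviations). Coherence is the plain mean of the map over the VA.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `cutoff_hz` | 0.5 | Hz | separates adult free-breathing respiration (~0.2–0.4 Hz) from resting cardiac frequency (>= 0.7 Hz) |
| `band` | (0.7, 3.0) | Hz | 42–180 bpm, covers rest and exercise heart rates |
| `numerator_halfwidth` | 0 | bins | the index names exactly the ± `f_c` bin pair; widening is an explicit option, never silent |
| `mode` | `"modulus"` | — | \|r\| keeps the map in [0, 1] and is invariant to per-voxel phase; `"signed"` (Re r) retained as an option |
| `aggregate` | `"roi_weighted"` | — | slices combined by ROI-voxel-weighted mean; unweighted mean and single-slice rules available (no published combination rule exists) |

Numerical conventions fixed across the package: 0-based frame indexing,
seconds, Hz, ml; unitary DFT; ideal (brick-wall) zero-phase spectral mask
for the high-pass filter, zeroing every bin with |f| < cutoff including
DC — exactly linear, idempotent, and transparent under the periodicity
index (zeroed bins contribute nothing to its denominator, which also
resolves the double-counting the paired sum would otherwise apply to the
DC bin). No taper is applied by default; tapering changes leakage and
must be requested explicitly.

## The synthetic beating heart

`generate_series()` renders two disk-shaped chambers per slice (LV and a
smaller RV), each wrapped in a myocardial annulus, on a 64 x 64 grid
(default) with 1.5 mm pixels, 8 mm slices and 2 mm gaps. Its stated
world:

* **Heartbeats.** RR intervals are `(60/HR) * (1 + sigma_RR * e)`,
  `e ~ N(0,1)`, floored at 0.3 of the mean interval (no non-physical
  beats), appended until they cover the window. The endocardial radius
  follows `r(t) = r_ED - (r_ED - r_ES) * s * c(phi)` with `c` a
  raised-cosine pulse occupying the systolic fraction (0.35 by default) —
  smooth (C1), so no spectral artifacts beyond the modeled physiology.
* **Respiration.** Whole-frame amplitude modulation
  `1 + a_resp * sin(2 pi f_resp t)` at 0.25 Hz, amplitude 0.1.
* **Noise.** Independent complex Gaussian noise per voxel per frame
  (default SD 5 against blood 100 / myocardium 40), giving the reduced
  SNR regime of real-time imaging. No noise magnitude is published for
  the source acquisitions; this is a free parameter, not a calibrated
  claim.
* **Complex phase.** Constant per tissue compartment plus a small smooth
  in-plane ramp, so spectra are genuinely non-conjugate-symmetric.
* **Dyssynchrony.** A wedge of myocardial angles (about each chamber
  centre) follows the same contraction waveform delayed by
  `desync_lag_s`. Default lag 0.3 s: a severe-LBBB-scale activation
  delay, a large fraction of the systolic pulse. Shorter lags mostly
  comb-filter the *harmonics* of the ROI-averaged signal and can
  paradoxically raise the periodicity of a dyssynchronous heart; at
  ~0.3 s the delayed block suppresses the fundamental of the mixture,
  which is the regime the presets are meant to represent.
* **Presets.** `phantom_preset("healthy")`: sigma_RR 0.03, full
  contraction, no desync. `phantom_preset("hf")`: sigma_RR 0.12,
  contraction scale 0.6, desync fraction 0.3. These produce the
  qualitative healthy-vs-failing ordering of both indices; they claim no
  cohort's exact numbers.

What the phantom does **not** emulate: k-space sampling, coil
sensitivities and undersampling artifacts; through-plane (longitudinal)
motion; papillary muscles and trabeculation; realistic myocardial
texture. A green simulation test therefore establishes that the
*analysis* behaves as specified on data with the assumed statistical
structure — not that the indices are validated on human images.

## What a perfect heart scores

With zero noise, zero jitter, zero respiration and an integer number of
cycles per window, periodicity still reflects waveform harmonics: the
default (35% systole) pulse scores ~0.72, and only the sinusoidal-motion
configuration (systolic fraction 1) exceeds 0.95. Coherence is bounded by
anatomy, not noise: blood-pool voxels interior to the ES radius never
change, contribute r = 0 (they stay in the map so M remains the anatomy
size), and wall-crossing voxels are duty-cycle square waves that are not
linear in the reference — the near-ideal ceiling is ~0.83–0.88, not 1.

## Limitations of the global reference

Because the reference signal is the average over the whole ROI, spatial
coherence is *not* monotone in the desynchronized fraction of the wall.
It falls steeply as a minority block desynchronizes (0.52 to 0.29 between
fractions 0 and 0.3 under the simulation defaults), but once the delayed
block is the majority the reference re-aligns with it and coherence
recovers (by relabeling symmetry it must return to its baseline at
fraction 1; the minimum sits near one third). The acceptance suite
asserts the strictly-decreasing expectation over {0, 0.3, 0.6} as stated
and the 0.3 -> 0.6 leg fails by design of the method itself; this is a
real property any global-reference coherence measure inherits, worth
knowing before interpreting coherence in severely dyssynchronous
ventricles.

## Statistics layer

* **Normality**: Anderson–Darling with mean and variance estimated,
  small-sample-adjusted statistic `A*^2 = A^2 (1 + 0.75/n + 2.25/n^2)`
  and the standard piecewise-exponential p-value approximation for the
  estimated-parameters case.
* **Group comparison**: Welch (unequal-variance) t with a one-tailed
  p-value in a direction declared in advance. Welch rather than pooled:
  the safer default when no variance homogeneity is claimed; a pooled
  variant is not offered because the two differ testably and silently.
* **Quartiles**: linear interpolation between order statistics (R type
  7), stated because box-plot conventions differ.
* alpha = 0.05, no multiple-testing correction (mirroring the analysis
  workflow this package reproduces); noted, not endorsed.

Type-I calibration of the one-tailed Welch layer is checked under
i.i.d. normal null cohorts (n = 12 per arm, 1000 replicates) rather than
1000 phantom-cohort simulations, which would cost two orders of magnitude
more compute for a property of the t-layer, not the imaging pipeline.

## Degenerate inputs and tie-breaks

Empty ROI (ED = ES) is an error that callers use to reject a slice;
ES voxels outside ED are subtracted literally with a warning. Zero-variance
voxel series get r = 0 and a flagged count. Spectral peak ties break
toward the lower frequency (within 1 part in 1e12 of the maximum, so
equal-amplitude tones tie-break deterministically under floating point).
Cutoffs at or above Nyquist, empty search bands, all-zero signals and
non-positive volumes are rejected with diagnostic errors.

## Interchange formats

NIfTI-1 (single-file `.nii`, uncompressed) carries images and masks;
complex series travel as paired real/imaginary float64 volumes (or one
magnitude volume with a recorded flag), masks as uint8, with a JSON
sidecar for frame spacing and the inter-slice gap (which NIfTI cannot
represent). The reader/writer is minimal and self-contained (uint8,
int16/32, float32/64, <= 5 dims, both endiannesses on read); output was
cross-checked against an independent NIfTI implementation during
development. Signals and cohort tables are CSV; every analysis bundle
embeds the fully resolved configuration and package version, and all
randomness flows from explicit seeds, so reruns are bit-identical.

## Scaled-down simulation sizes

The default phantom matches the acquisition scale it emulates (64 x 64,
384 frames at 20 ms, 3 slices). Simulation studies in the test-suite and
the cohort analog run a size-reduced variant (40–48 px, 192–256 frames,
1 slice) purely to fit the compute budget; preset physiology is
identical, and all oracle-equality checks are size-independent.
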