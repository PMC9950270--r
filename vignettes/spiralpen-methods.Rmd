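---
title: "spiralpen: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spiralpen: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralpen)
```

This vignette documents how the pipeline works, why its parameters have the
values they have, what the synthetic generator does and does not emulate, and
the numerical choices that affect reproducibility.

## Signals and preprocessing

A trial is a uniformly sampled 50 Hz recording of tri-axial acceleration
(m/s², gravity included), tri-axial angular velocity (deg/s) and pen-tip
force (arbitrary device units — the load cell is uncalibrated, so only
within-cohort comparisons of force levels are meaningful).

**Channel combination.** All 1-D indicators consume the Euclidean norm
√(x²+y²+z²) of each tri-axial sensor. The norm is invariant to how the
subject holds the pen (any rotation of the device frame), which matters
because grip orientation is uncontrolled. A consequence worth knowing: the
norm responds linearly to oscillations only around a dominant component
(gravity for the accelerometer, the mean rotation rate while spiraling for
the gyroscope); an isolated oscillation on a single axis with no offset is
rectified. Handheld drawing always provides the offset, and the synthetic
generator reproduces it.

**Band-pass.** Kinematic norms are filtered to 2–12 Hz — below 2 Hz lives
the voluntary drawing oscillation (≈0.5–1 loops/s), above 12 Hz mostly
sensor noise; Parkinsonian rest/action tremor sits at 4–7 Hz. The filter is
a 4th-order Butterworth band-pass (designed as `signal::butter(2, ...)`,
i.e. order 4 overall) applied forward–backward for zero phase lag. Before
filtering, the series mean is removed and the series is extended by odd
(point-reflected) padding — up to 2 s per edge — so the low-frequency
startup transient of the 2 Hz edge dies inside the padding. Band-passed
norms are explicitly mean-removed afterwards: finite-window IIR filtering
leaves a small DC residue that would otherwise violate the zero-mean
contract downstream.

**Tilt.** Gravity direction is estimated by low-pass filtering the raw
acceleration (2nd order, 1 Hz, zero phase); tilt is the angle between that
vector and the pen's long axis (device *z* by default, configurable), in
degrees. Recordings whose gravity estimate collapses (‖g‖ < 0.1 m/s²) are
rejected as free-fall artifacts.

**Strokes and quality control.** Pen–paper contact is detected from the
force channel with an adaptive threshold, `max(0.05 × 95th percentile,
1e-3)`, and 2:1 hysteresis (leave contact at half the entry threshold), so
the rule survives the unknown force scale. Candidate strokes shorter than
100 ms are merged across sub-100 ms gaps or dropped as contact bounce. Pen
lifts are counted only strictly between the first and last stroke — leading
and trailing air time is not a lift. A trace with more than 20 lifts is
excluded from analysis; 20 exactly is kept (the rule is a strict
inequality).

## Tremor extraction (EMD)

The tremor component is obtained from the mean-removed acceleration norm by
empirical mode decomposition: standard sifting with cubic-spline envelopes
(end effects handled by mirroring the two outermost extrema past each edge),
the standard-deviation stopping criterion ≤ 0.2 or at most 50 sift
iterations, and at most 10 IMFs. These constants are fixed in code, making
the decomposition fully deterministic. Each IMF gets a dominant frequency
(argmax of its Welch PSD); the tremor series is the **sum of all IMFs whose
dominant frequency falls in 2–12 Hz** (the same band as the kinematic
filter). Summing all in-band IMFs, rather than picking one, is robust to
mode splitting. The residual is defined as input − tremor, so the
decomposition is exactly complete. If no IMF lands in band, the tremor
series is zero, its peak frequency is undefined, and every `_T` indicator
becomes missing rather than a fabricated zero.

## Indicators

Time-domain indicators are computed on the concatenated on-paper samples
(force is undefined mid-air). Spectral and tremor indicators instead use the
contiguous span from first to last contact: splicing out mid-air gaps would
create step discontinuities that corrupt spectra and EMD far more than the
brief gaps themselves do.

* **Extrema** (used by `NC_*`, `ConsPeakDiff_*`): strict sign changes of the
  first difference, plateaus resolved to their first sample, with a
  prominence guard of 2% of the series' interquartile range — the guard
  repeatedly removes the adjacent extremum pair with the smallest swing, so
  alternation is preserved and sensor noise does not inflate counts.
  Consecutive-peak differences use absolute swings; coefficients of
  variation use the population (n-denominator) standard deviation
  throughout.
* **SPARC** is computed per its source definition on the band-passed norm:
  zero-padded FFT (grid ≤ 0.05 Hz), normalized magnitude spectrum, adaptive
  cutoff at the highest frequency ≤ 20 Hz where the spectrum still reaches
  the threshold (10–50% of peak, six variants), trapezoid integration of
  the arc length. Raising the threshold shortens the integrated arc, so
  SPARC is monotonically non-decreasing in the threshold.
* **LDLJ** uses the dimensionless form −ln((T/s_peak²)·∫ṡ²dt) with a
  central-difference derivative, which makes it invariant to amplitude
  scaling for any input order.
* **Welch PSD**: Hann window, 500-sample segments, 50% overlap, 0.1 Hz
  grid; one-sided scaling satisfies Parseval to within taper bias (checked
  at 10% in tests). Shorter series fall back to a single zero-padded
  segment and are flagged. Relative band powers (0–2, 2–4, 4–7, 8–12 Hz;
  half-open bands, the 7–8 Hz gap preserved as printed in the field's
  reporting convention) are computed on the **raw mean-removed norms**, not
  the band-passed ones: after a 2–12 Hz band-pass the 0–2 Hz band would be
  empty by construction, which contradicts the reported control-group
  values of ≈0.5–0.7 — so the band-pass cannot precede the relative-power
  denominators.
* **"Around the peak"** means ±1 Hz everywhere it occurs
  (`RPW_G_filt_max`, `RMS_G_filt_max`, `SNR_T`, `MHP_T`); one knob,
  `peak_halfwidth_hz`. `MHP_T` is the natural log of the mean tremor PSD in
  that window with the tremor expressed in mm/s² — a documented stand-in
  where the literature does not pin the band or log base. `SNR_T` is
  reported linear, not dB. The spectral outlier level divides the
  peak-minus-mean distance by the PSD standard deviation over 2–12 Hz;
  the normalization makes PD ≈ 4 vs control ≈ 3 magnitudes plausible and
  is stated here prominently because the field's phrasing ("distance
  between peak and mean") leaves it open.
* **Regularity**: ApEn(m = 2, r = 0.2σ, Chebyshev distance, self-matches
  included); recurrence analysis with embedding dimension 3, delay at the
  first autocorrelation zero-crossing (capped at 10 samples), recurrence
  threshold 20% of the embedded cloud's maximum pairwise distance, DET over
  diagonal lines of length ≥ 2, input strided down to ≤ 2000 samples to
  bound the O(n²) matrix. The tremor stability index band-passes the tremor
  to 2–12 Hz, segments cycles at positive-going zero crossings (sub-sample
  interpolated) and reports the IQR of consecutive-cycle frequency
  differences. Note that reconstructing a waveform and re-filtering it
  smooths cycle-to-cycle frequency jumps (FM sideband truncation), so the
  waveform-path TSI of an alternating 4/5 Hz tone is attenuated below the
  list-reduction value of 2.0 — `tsi_from_cycle_freqs()` exposes the exact
  reduction.

## The synthetic generator

No public recording set exists for this device, so `generate_cohort()`
produces cohorts with the statistical structure the analysis assumes:

| Parameter (preset)        | PD     | control | meaning                          |
|---------------------------|--------|---------|----------------------------------|
| tremor amplitude (median) | 0.5    | 0.03    | m/s², lognormal (sdlog 0.35) per subject |
| tremor frequency          | U(4,7) | U(4,7)  | Hz, per subject                  |
| cycle jitter sd           | 0.4    | 1.5     | Hz — PD tremor is frequency-stable |
| ripple amplitude          | 0.12   | 0.04    | m/s² at 10 Hz (smoothness deficit) |
| force mean                | 8      | 12      | device units — PD presses less   |
| force CV                  | 0.25   | 0.15    | PD force is more variable        |
| force oscillation rate    | 3.74   | 3.09    | extrema/s, the reported group means |
| pen lifts (Poisson mean)  | 0.8    | 2.2     | per trial                        |
| duration / rate           | 30 s / 50 Hz | same | two trials per subject      |

Tremor is **phase-continuous with per-cycle frequency jitter** (not additive
phase noise), so the TSI has a direct ground-truth knob. Tremor and ripple
are directed along the pen axis and ride on the gravity/rotation offsets, so
they survive the norm reduction linearly. The drawing oscillation (0.8 Hz)
carries a weak 3rd harmonic at 2.4 Hz, giving controls realistic in-band
low-frequency content — without it, control band-passed norms would be pure
noise and the smoothness contrasts would be artifacts of an empty band.
Subject-level scatter (lognormal on amplitudes, force level and CV; normal
on the force oscillation rate) keeps group distributions overlapping instead
of point masses. Synthetic clinical scores are monotone noisy transforms of
the injected tremor amplitude, standardized within the patient group and
calibrated to a Spearman correlation of ≈0.45 with the latent severity —
only their rank structure is meaningful.

What the generator does **not** emulate: real spiral biomechanics (no
template-following error model, no pen-tip trajectory), inter-trial learning
effects, medication-state fluctuations, sensor drift, or realistic
correlations *between* indicator families beyond those induced by the shared
latent severity. Passing tests therefore show that the pipeline measures
what it claims on signals with known structure — not that the synthetic
effect sizes match any clinical cohort's.

## Statistics

Trial indicators are averaged per subject and hand (single-trial subjects
pass through flagged; an indicator missing in one trial is averaged over the
available ones). Group comparison is gated on the Lilliefors test at α =
0.05 **in both groups** (AND rule): both normal → Welch t-test with mean ±
sd summaries, otherwise Mann–Whitney with median (IQR). No multiplicity
correction is applied by default, matching common reporting in this
literature; `p_adjust = "BH"` enables Benjamini–Hochberg. Spearman
correlations with clinical scores run per hand in the patient group, with
strength labels |ρ| ≤ 0.3 weak, < 0.7 moderate, ≥ 0.7 strong (a total
partition of [0, 1]). The sample-size helper uses the Fisher-z
approximation n = ⌈((z₁₋α/₂ + z_power)/atanh ρ)² + 3⌉.

## Classification and attribution

Leave-one-out cross-validation with three backends behind one interface:
ridge-regularized logistic regression (glmnet, α = 0, λ = 1/n — the
L2-penalized fit is the appropriate linear reference when p ≈ n), random
forest (500 trees) and gradient-boosted trees (xgboost, 100 rounds, depth 3,
η = 0.1). The "significant indicators" subset is recomputed **inside every
fold** on the training rows only; selecting once on the full table leaks the
held-out subject's data into its own feature selection, and the test suite
demonstrates on null data that un-nested selection can only inflate apparent
accuracy. Missing indicator values are imputed with training-fold medians.

Attribution: TreeSHAP via xgboost's `predcontrib` predictions for the
boosted trees (per-subject signed contributions; positive pushes toward PD),
coefficient × centered-value for the linear model; random forest has no
Shapley backend here and errors informatively. xgboost computes
contributions in single precision, so the additivity identity (attributions
+ base value = margin) holds to ≈5e-6 on margins of order 5; tests assert it
at 1e-4 absolute.

## Numerical choices and degenerate inputs

Trapezoid integration for all band powers and the SPARC arc; ties in
extrema detection resolved to the first plateau sample; attribution rank
ties broken by column order. Degenerate inputs return missing rather than
inventing values: zero-peak series (LDLJ), all-zero series (SPARC), < 3
extrema (`ConsPeakDiff`), zero-mean tilt (CV), flat spectra (outlier level),
undefined tremor peak (all `_T` indicators). Constant series are defined
where a limit exists: ApEn = 0, RR = DET = 1.

## Problem sizes used by the test suite

The effect-direction suite runs the default presets at the design cohort
size (29 + 29 subjects, two 30 s trials) over 50 seeds, extracting only the
indicators under test. Type-I calibration under exchangeable (null) presets
uses 200 replicates of 8 + 8 subjects with 12 s trials and a single cheap
indicator — the quantity calibrated is the test's false-positive rate, which
does not depend on cohort size. Oracle-equivalence checks run on ≤ 500-sample
instances where the O(n²) brute-force references are exact.

## Known limitations

The force scale is device-arbitrary, so absolute force thresholds and
levels do not transfer across devices. Whether execution time should
include mid-air time is a convention; we include it (start-to-end span).
The EMD variant is the classic one — no ensemble/CEEMDAN, so mode mixing is
possible on signals with intermittent tremor. The recurrence suite is
limited to RR and DET (no laminarity or trapping time). LOOCV accuracy on
small cohorts has high variance and the synthetic presets are deliberately
separable; the reported classification numbers characterize the pipeline,
not expected clinical performance.
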