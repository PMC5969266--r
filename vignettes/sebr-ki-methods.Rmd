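---
title: "Methods: from eye blinks and dynamic PET to calibrated correlation evidence"
author: "sebrKi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from eye blinks and dynamic PET to calibrated correlation evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sebrKi)
```

`sebrKi` measures two quantities per subject — spontaneous eye blink rate
(sEBR, blinks/min, from electro-oculography) and striatal dopamine
synthesis capacity (the [18F]DOPA influx constant Ki, min⁻¹, from
reference-region Patlak analysis) — and then asks, with frequentist and
Bayesian machinery, how they relate across a cohort. This vignette
documents the models, the defaults and why they were chosen, the
numerical conventions, and what the synthetic-data validation does and
does not demonstrate.

## 1. Blink detection from EOG

### Model and assumptions

A blink appears on the vertical EOG channel (vEOG) as a smooth, large
(hundreds of μV) deflection lasting roughly 200–400 ms. Saccades and
facial-muscle activity contaminate the channel; saccades are visible on
the horizontal channel (hEOG), which carries no blink signal. The
detector assumes a uniform sampling grid (50 Hz or faster, so the 20 Hz
filter edge is below Nyquist; recordings here use 100 Hz).

### Processing chain

1. **Rectify, then filter.** The channel median is removed, the absolute
   value taken, and a band-pass of 0.5–20 Hz applied. The filter is a
   4th-order Butterworth run forward and backward (`signal::filtfilt`),
   i.e. zero-phase: causal filtering would delay the waveform and bias
   every onset estimate by a filter-dependent lag. The high-pass edge at
   0.5 Hz removes electrode drift and DC; 20 Hz removes line noise and
   most EMG.
2. **Threshold rises.** An event triggers wherever the signal rises by at
   least `thresholdUv` (default 100 μV) relative to its minimum over the
   trailing `windowMs` (default 400 ms) interval. The 200 and 300 μV
   settings are the conservative modes: fewer muscle-artifact false
   positives at the cost of missing small blinks, which removes any need
   for manual editing.
3. **Peak-anchored event times.** Within a window after the trigger, the
   event peak is the local maximum; the baseline is the pre-peak window
   minimum; the onset is the last pre-peak sample within 5% of the event
   amplitude above baseline. Anchoring baseline and onset at the *peak*
   rather than the trigger makes the reported times independent of the
   detection threshold, so event lists at 100/200/300 μV nest cleanly.
   With the 5% rule the onset estimate sits ~30 ms after the true start
   of a raised-cosine rise — well inside the ±50 ms matching tolerance
   used in validation.
4. **Refractory merge.** Events whose onsets fall within 200 ms are
   merged (keeping the higher peak). This prevents double counting of
   biphasic deflections; 200 ms is half the detection window and shorter
   than any physiological inter-blink interval.
5. **Saccade rejection.** An event whose peak lies within ±100 ms of an
   hEOG excursion exceeding `heogThresholdUv` (default 100 μV from the
   channel median) is flagged `rejected(saccade)`. This is an explicit,
   reproducible stand-in for the visual inspection step of manual
   workflows; the conservative modes disable it entirely.
6. **Data loss and the rate.** Samples in constant runs at the amplifier
   rail (|v| ≥ 500 μV) longer than 100 ms, or non-finite samples, count
   as lost (amplifier saturation). sEBR is blinks per *exploitable*
   minute, so partially lost recordings (e.g. 3.5 of 6 min usable)
   remain analysable; subjects are excluded only when loss is strictly
   greater than 50% of the recording. Two raters' values are averaged
   after computing Cronbach's α = 4·cov(a,b)/var(a+b) as reliability.

```{r blink-demo}
rec <- simulateEog(randomEogTruth(30, noiseSd = 10, seed = 1))
ev <- detectBlinks(rec)
computeSebr(ev, assessDataLoss(rec)$exploitableMinutes)
```

## 2. Patlak analysis

### Model

For a tracer trapped irreversibly in tissue, with a reference region
devoid of trapping (cerebellum), the transformed coordinates

* x(t) = ∫₀ᵗ C_ref(s) ds / C_ref(t)  ("normalized time", minutes)
* y(t) = C_tissue(t) / C_ref(t)

become linear once the reversible compartments equilibrate with plasma:
y = Ki·x + V. The slope Ki (min⁻¹) indexes dopamine synthesis capacity;
the intercept is scaled to the tracer distribution volume of the
reference region.

### Numerical conventions

* Curves are evaluated at **frame mid-times**; the cumulative integral is
  the trapezoidal rule **anchored at (0, 0)** — activity is zero at
  injection. One shared operator (`cumTrapz0`) serves both the generator
  and the transform, which makes the noiseless relation exactly linear on
  the frame grid and lets tests demand slope recovery at 1e-10 relative
  error rather than "close".
* The fit window is mid-time ∈ [24, 89] min, the standard linear phase
  for 89-min [18F]DOPA scans; any sub-window gives the identical slope on
  noiseless data.
* The line fit is unweighted OLS; frame-duration weighting is
  deliberately not the default because the late frames have equal (5 min)
  durations and the added complexity buys nothing in this design.
* The voxel-wise map shares its x axis across voxels, so the whole-volume
  fit is a single matrix product; a looped per-voxel path exists only in
  tests as an oracle. The reference TAC is the unweighted mean over
  reference-mask voxels. Voxels with non-positive reference activity or
  non-finite data receive a NaN sentinel and are excluded (and counted)
  in ROI summaries.
* The striatal mask keeps template voxels ≥ mean + 3 SD, with mean and SD
  over **all finite template voxels**. On a whole-brain Ki template the
  ≥ 3 SD tail isolates the striatum, where trapping is maximal.

## 3. Cohort statistics

* **Normality gate.** One-sample Kolmogorov–Smirnov against a normal with
  the sample mean/SD; p < 0.05 routes the analysis to ranks. (With
  estimated parameters the KS test is conservative; it is used here as a
  gate, not as a calibrated test.)
* **Spearman ρ** is the Pearson correlation of mid-ranks; p-values are
  exact (n ≤ 9, no ties) or from the t-approximation
  t = ρ√((n−2)/(1−ρ²)).
* **Partial regression.** The slope of sEBR in the multiple regression of
  Ki on sEBR + age + group, with a subject-level (row-resampling)
  percentile bootstrap: 2000 replicates by default, two-sided p =
  2·min(P(b* ≤ 0), P(b* ≥ 0)) with add-one smoothing. Percentile
  intervals were chosen over BCa for transparency at these small n;
  singular resamples are dropped and counted.
* **Bayes factors.** BF₁₀ = ∫ L(ρ; r, n) π(ρ) dρ / L(0; r, n), with L the
  exact Fisher/Hotelling sampling density of the Pearson correlation
  (implemented with an in-package Gauss ₂F₁ series; the density
  integrates to 1 to 1e-8) and π a stretched beta(1/κ, 1/κ) on (−1, 1).
  κ = 1 is the flat prior; the directional tests truncate to (0, 1) or
  (−1, 0) and renormalize. Quadrature is adaptive with relative tolerance
  1e-6 (the beta endpoint singularities for κ > 1 are integrable).
  Because the prior is symmetric, the two-sided BF equals the mean of the
  two one-sided BFs — used as an internal consistency check. The Bayes
  factor is evaluated at the sample Pearson r by default; a rank-based
  mode (`bfOn = "rank"`) feeds the Pearson r of the rank-transformed data
  instead, since published workflows are ambiguous on this point. The
  robustness curve re-evaluates the directional BF over a κ grid
  (default 0.1–2) and reports where BF₀₁ ≥ 3 persists.
* **Voxel-wise FWE.** Per-voxel t statistics for the predictor slope,
  with family-wise error control by the permutation distribution of the
  maximum |t| over the mask (B seeded permutations of the predictor;
  p_FWE = (1 + #{max|t|_b ≥ |t|})/(B + 1)). Permutation max-T was chosen
  over random-field theory because it is exact under exchangeability,
  assumption-light, and directly testable: its family-wise error rate can
  be measured on null simulations. Voxel indices are 0-based in
  world-coordinate computations.
* **Power.** The power of the correlation test is computed from the exact
  sampling density of r (no Fisher-z approximation): the t-test rejection
  region is mapped to the r scale and integrated. The sample-size search
  walks n upward from 4. The default is one-tailed α = 0.05, matching the
  directional form of a replication hypothesis about a positive
  correlation; a `tails = 2` flag is provided.

```{r power}
powerSampleSize(0.62, targetPower = 0.95, alpha = 0.05, tails = 1)
```

## 4. The synthetic-data module

The generators define the conditions under which the pipeline is
validated:

* **EOG** (`simulateEog`): blinks are raised-cosine deflections, 400 ms
  wide, peaking 200 ms after onset — smooth, matched in time scale to the
  detection window, but deliberately *not* the detector's model (the
  detector knows nothing about the waveform). Saccades are ±200 μV steps
  on hEOG; saturation clamps vEOG at a +500 μV rail; both channels get
  white Gaussian noise (default SD 10 μV; validation also runs at
  20 μV). Defaults: 6-min recordings at 100 Hz, ~400 μV blinks.
* **PET** (`simulateReferenceTac`, `simulateTissueTac`,
  `simulateDynamicVolume`): the reference input is a gamma-variate
  (peak at 10 min, well before the 24-min window start; any smooth
  rise-then-decay curve works for the linear-phase analysis, and no
  input-function estimate is implied). Tissue curves are built *exactly*
  on the Patlak relation with the shared integral operator; frame noise
  is additive Gaussian with SD = noiseSd·activity/duration, a crude
  count-statistics proxy whose magnitude is a free knob, clipped at zero.
  Default frames: 24 frames over 0–89 min (1–5 min durations).
* **Cohorts** (`simulateCohort`): a Gaussian copula links a gamma sEBR
  marginal (mean ≈ 17 blinks/min, SD ≈ 8 — typical resting values) to a
  normal Ki marginal (0.012 ± 0.0015 min⁻¹, typical striatal [18F]DOPA
  values). The latent Pearson parameter is set by the exact
  bivariate-normal inversion r = 2·sin(π·ρ_S/6), so the **population**
  Spearman correlation equals the target. Group proportions default to
  9 controls / 11 gamblers per 20; age is uniform on 22–54; optional
  `ageBeta` / `groupDelta` shift Ki means (default 0, keeping the copula
  calibration exact).

Every generator is a pure function of (parameters, seed), and seeds are
handled with save/restore so library calls never disturb the caller's
RNG stream.

**A calibration subtlety worth knowing.** The copula targets the
*population* Spearman ρ_S. The *sample* Spearman estimator is biased
toward zero in small samples: for a bivariate-normal copula its
expectation is (6/(π(n+1)))·[asin(r) + (n−2)·asin(r/2)] (Moran's
classical result), which at n = 20 and ρ_S = −0.5 is ≈ −0.478, a bias of
≈ +0.022. Simulation studies that average sample Spearman coefficients
across cohorts will therefore sit visibly inside the population target
at these sample sizes; the generator is calibrated to the population
value, and the package's validation checks the estimator distribution
against Moran's expectation, not against the naive assumption of
unbiasedness. This is a property of the estimator, not an error term one
should re-tune the generator to absorb.

### What the synthetic validation does not show

The generators emulate signal structure, not physiology or physics: no
eyelid biomechanics, EMG spectra, or real saccade kinematics; no scanner
effects (attenuation, scatter, motion, partial volume, reconstruction
artifacts) and no real input-function variability; cohorts have clean
marginals and exactly Gaussian dependence. Passing tests demonstrate that
the *algorithms* are correct and calibrated under these conditions — not
that real recordings will be this well behaved. The 50% data-loss rule,
in particular, is exercised with synthetic saturation whose rail behavior
is idealized.

## 5. Problem sizes used in validation

The shipped test-suite checks run at sizes chosen to make Monte-Carlo
error small relative to the tolerances while keeping a laptop run
comfortable: 100 six-minute recordings for detection F1 (≥ 0.95 against
planted onsets at 400 μV amplitude / 20 μV noise), a 20×20×20 noiseless
phantom for voxel-wise exactness, a 2×10⁵–10⁶-draw Monte-Carlo prior
integration as the Bayes-factor oracle (1% agreement), 500 null
cohorts × 500 permutations for the family-wise error rate of the
voxel-wise test (nominal 5%), and 10⁴ cohorts of n = 20 for the
end-to-end Spearman recovery distribution.

## 6. Known limitations

* The Patlak implementation is reference-region only; arterial-input
  Patlak, realignment, coregistration and spatial normalization are out
  of scope (inputs are assumed aligned).
* Events are detected on the rectified signal, so blink amplitude is
  measured after rectification and filtering; absolute amplitudes are
  not comparable across filter settings.
* The Kolmogorov–Smirnov gate with estimated parameters is conservative;
  it mirrors common practice rather than a recommended test (Lilliefors
  correction would be the stricter choice).
* Permutation FWE assumes exchangeability of subjects under the null;
  with strong covariate structure a Freedman–Lane scheme would be
  preferable and is not implemented.
* `spearmanCor` requires complete cases and n ≥ 4; ties are handled by
  mid-ranks with the t-approximation.
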