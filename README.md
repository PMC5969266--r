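# sebrKi

Spontaneous eye blink rate (sEBR) is widely used as a cheap behavioural
proxy for striatal dopamine function. Testing whether that proxy actually
tracks an *in vivo* dopamine measure requires two very different
measurement chains — blink detection from electro-oculography (EOG), and
dopamine synthesis capacity (the influx constant Ki) from dynamic
[18F]DOPA PET — plus a statistical layer able to quantify evidence for the
*absence* of the expected positive correlation, not just its presence.
`sebrKi` implements that whole chain as tested, reusable R functions, with
a synthetic-data module that generates every input with known ground truth
so the pipeline can be validated end to end without any recordings.

It is aimed at PET/psychophysiology researchers who want a transparent,
scriptable alternative to the usual mix of vendor EOG tooling, in-house
Patlak programs, SPM and JASP.

## What it computes

**Blink rate.** The vertical EOG channel is rectified and band-pass
filtered (0.5–20 Hz, 4th-order zero-phase Butterworth); blinks are
voltage rises of ≥ 100 μV within 400 ms (200/300 μV conservative modes);
events coincident with horizontal-channel (saccade) deflections are
rejected; amplifier-saturation stretches are counted as data loss, and
sEBR = blinks per *exploitable* minute. Subjects lose their data when
loss exceeds 50% of the recording. Two raters' measures are averaged with
Cronbach's α as reliability.

**Ki.** For an irreversibly trapped tracer, plotting
y(t) = C_tissue(t)/C_ref(t) against the "normalized time"
x(t) = ∫₀ᵗ C_ref(s) ds / C_ref(t) becomes linear late in the scan; the
slope of the 24–89 min ordinary-least-squares line is the net influx
constant Ki (min⁻¹), computed per region or per voxel
(reference region: cerebellum). A whole-brain Ki template thresholded at
mean + 3 SD yields the striatal region of interest.

**Statistics.** Kolmogorov–Smirnov normality gate; Spearman ρ (exact
p for n ≤ 9); bootstrapped partial regression of Ki on sEBR with age and
group covariates; correlation Bayes factors
BF₁₀ = ∫ L(ρ; r, n) π(ρ) dρ / L(0; r, n) with the exact sampling density
L of the Pearson correlation and a stretched beta(1/κ, 1/κ) prior on
(−1, 1) — flat for κ = 1, truncated for the directional tests — with a
prior-width robustness curve; voxel-wise regression with family-wise
error control by the permutation distribution of the maximum |t|; and an
exact-distribution power analysis for correlation tests.

## Worked example

```r
library(sebrKi)
rep <- runPipeline(defaultRunConfig(seed = 42))
print(rep)
```

```
sEBR-Ki pipeline report
  subjects: 20 recruited, 20 retained
  normality gate: KS p = 0.207 -> parametric
  Spearman rho = -0.2582, p = 0.2717 (n = 20, t-approximation)
  BF01 against a positive correlation: 7.414
  BF10 for a negative correlation: 1.001
  Partial regression: beta[sebr] = -3.234e-05 (95% bootstrap CI -0.000105 to 3.321e-05, p = 0.362, 2000 reps)
```

This simulates a 20-subject cohort whose population Spearman correlation
between sEBR and Ki is −0.5, renders each subject's 6-min EOG trace and
dynamic PET time-activity curve, re-measures both (blink detection;
Patlak fit), and runs the statistical layer on the measured values. Here
the sample correlation happens to land at −0.26 (n = 20 is small); the
directional Bayes factor says the data are ~7 times more likely under
"no positive correlation" than under a positive one, while the evidence
for a specifically negative relationship is equivocal (BF₁₀ ≈ 1.0). The
partial-regression slope is in Ki units (min⁻¹) per blink/min.

Single pieces work standalone:

```r
powerSampleSize(0.62)
#> Exact correlation power analysis: n = 12 (power 0.9568 at rho = 0.787, alpha = 0.05, 1-tailed)
bayesFactorCorrelation(-0.5, 20, side = "positive")
#> Correlation Bayes factor (positive, kappa = 1): BF10 = 0.09466, BF01 = 10.56  (r = -0.500, n = 20)
```

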