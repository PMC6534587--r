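---
title: "Quantitative fluorescence-intensity staging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative fluorescence-intensity staging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

Autofluorescence imaging of oral mucosa under ~425 nm excitation yields an
8-bit RGB image in which essentially all of the biological signal sits in
the green channel. `fiquant` works throughout with the **G-value**, the
green-channel intensity (0–255) of one pixel. The unit of analysis is the
**measurement line**: an ordered sample of `n` G-values taken from the
tongue apex (A) to the tongue root (R) — 200 pixels in the rat
carcinogenesis model, 50 pixels for human measurement sites. Anatomical
structures that must not enter the statistics (notably the crescent-shaped
"half-moon" structure of the rat tongue) are handled with a user-supplied
exclusion mask; automatic detection of such structures is deliberately out
of scope, since no reproducible segmentation rule exists for them.

Four histological stages are modelled: Control (normal epithelium), LGD
(low-grade dysplasia), HGD/CIS (high-grade dysplasia / carcinoma in situ)
and Cancer (invasive squamous cell carcinoma). Their characteristic
G-value signatures are: uniformly dark Control; bright, mildly scattered
LGD; dimmer, rougher HGD/CIS; and Cancer with wide scattering and dark
spots.

## The synthetic-data generator

No raw images from the original cohorts are deposited, so the package
ships a generator whose per-stage parameters are calibrated to the
published group statistics. For a stage with parameters
`(mean_g, between_sd, within_sd, axial_slope, slope_sd, spot_rate,
spot_depth, spot_width)` one animal's field is

```
pixel(x, y) = m + a (x - x_c) + eps(x, y) - spot(x)
```

* `m ~ N(mean_g, between_sd²)` — the animal's expected line mean;
* `a ~ N(axial_slope, slope_sd²)` — the realized apex-to-root gradient,
  centred on the line midpoint `x_c` so the gradient never shifts the line
  mean;
* `eps ~ N(0, noise_sd²)` — i.i.d. pixel noise;
* `spot(x)` — top-hat depressions of depth `spot_depth` and width
  `spot_width` at Poisson positions (`spot_rate` per 100 line pixels),
  spanning the image height; the expected depression is added back to the
  baseline so spots widen the distribution without biasing the mean.
  A Gaussian spot profile is available via `spot_profile = "gaussian"`.

### Why the within-line SD is decomposed

The published within-sample SD is a property of the *raw measured
profile*, which in real data already contains the axial gradient and the
dark spots. Treating it naively as the pixel-noise SD and then adding a
gradient on top would inflate the realized profile SD (for the Control
calibration, a 0.03 G/px slope over 200 px alone contributes an SD of
about 1.7 G). The generator therefore interprets `within_sd` as the
*target total* within-line SD and derives the pixel-noise component by
variance decomposition:

```
noise_sd² = within_sd² − E[a²]·var(x) − p(1−p)·spot_depth²,   p = spot_rate·spot_width/100
```

(`pixel_noise_sd()`). Calibrations whose gradient/spot components already
exceed the target total are rejected as infeasible. A consistency check on
this interpretation: combining the published between-animal and
within-line SDs gives pooled class SDs of 4.02 (Control) and 8.40 (LGD),
and the closed-form Gaussian AUC `Φ(22.1/√(4.02²+8.40²)) = 0.991` matches
the reported Control-vs-LGD discrimination of 0.99.

### Default presets

Rat cohort (`rat_stage_presets()`, 200-px lines, n = 10/11/15/14):

| stage | mean | between SD | within SD | slope ± SD | spots /100px (depth × width) |
|---|---|---|---|---|---|
| Control | 32.5 | 3.2 | 2.43 | +0.03 ± 0.01 | none |
| LGD | 54.6 | 7.5 | 3.79 | −0.03 ± 0.03 | 0.5 (8 × 3) |
| HGD/CIS | 46.1 | 6.2 | 3.68 | +0.002 ± 0.04 | 1.0 (8 × 3) |
| Cancer | 49.1 | 7.1 | 4.42 | −0.03 ± 0.04 | 1.5 (9 × 3) |

Means/between-SDs and within-SDs are the published group values; slope
means follow the per-group inclination summaries, and the slope SDs are
chosen so the sign mixtures reproduce the reported positive/negative
averages (e.g. HGD/CIS: mean 0.002 arising from ≈ +0.04 positive and
≈ −0.03 negative branches of `N(0.002, 0.04²)`). Spot rates/depths are
tuned once so pooled pixel ranges approximate the published per-group
ranges (17.4 / 39.1 / 56.1 / 40.2) while keeping the variance
decomposition feasible. The human presets (`human_site_presets()`, 50-px
lines) model the four single-patient sites with site means
37.4/40.6/44.1/36.2 and within-SDs 1.34/4.72/3.74/10.59; with one site per
stage there is no between-site replication, so `between_sd = 0`, no
gradient is imposed and the wide Cancer distribution is carried entirely
by `within_sd`.

Fields are kept at full precision in memory and clipped to [0, 255];
8-bit quantization happens only when rendering to PNG/TIFF, so tests can
separate quantization error (it adds variance 1/12 ≈ 0.08 G², inflating a
recovered Control SD of 2.43 by under 1%). Rendered images are RGB with
the signal in green and a fixed low red/blue backdrop; render → load round
trips are bit-exact. All randomness flows from explicit integer seeds;
per-animal seeds are derived deterministically from the cohort root seed,
so a cohort is reconstructible bit-exactly.

### What the generator does and does not emulate

It reproduces the published stage-level statistical structure: stage
means, between-animal spread, within-line SD, axial gradients with
realistic sign mixtures, widening pixel scattering, and dark-spot
depressions. It does **not** model within-image spatial autocorrelation
beyond the linear gradient and spots — pixels are otherwise independent —
nor tongue anatomy, excitation physics or keratin optics. Two practical
consequences: (i) pairwise profile concordance on synthetic cohorts is
lower than the published ≈ 0.85–0.89, because real profiles share bump
structure that independent noise cannot; (ii) passing parameter-recovery
tests validates the *estimators*, not the realism of tongue images.

## Analysis methods and numerical choices

* **Profile sampling** uses nearest-pixel lookup by default: G-values are
  8-bit categories, and interpolation would fabricate unobservable
  intensities. Bilinear interpolation is available via `method =
  "bilinear"`. Line width is 1 px.
* **Summaries**: the variation statistic is the sample SD with the N−1
  denominator; the median of an even-length profile is the midpoint of the
  two central order statistics. Group statistics pool all pixels of a
  stage (the published group extremes clearly span pixel-level values);
  per-animal aggregation is available by summarizing samples directly.
* **Scattering histograms** default to 1-G-value bins (the native
  quantization), right-open, with 255 closed into the final bin so counts
  are conserved.
* **Concordance**: all unordered profile pairs are correlated after
  aligning on normalized A→R position; unequal lengths are resampled to
  the shortest by even index selection. The reported group value is the
  mean over all pairs (the per-animal-then-group alternative is not used);
  p-values come from the t transform and are reported, never gated on.
* **Inclination line**: "the line at minimum distance from all measured
  intensities" is ambiguous between vertical and perpendicular distance;
  the default is ordinary (vertical) least squares, because intensity is
  regressed on a fixed pixel grid, with total least squares (SVD) provided
  as `method = "orthogonal"`. Both coincide on noiseless collinear data.
  Slopes with |a| < 1e-6 G/px are classed "zero" and excluded from both
  the positive and negative group averages.
* **ROC**: thresholds sweep all distinct observed values; the calling
  direction is chosen from the rank statistic so AUC ≥ 0.5 and is recorded
  in the output. The trapezoidal area equals the tie-corrected
  Mann–Whitney `U/(n₁n₂)` exactly. Cutoffs maximize Youden's J, with ties
  broken toward the midpoint of the two group means, and are reported as
  the midpoint between the selected threshold and the adjacent observed
  value; a comparison with max J ≈ 0 is flagged degenerate. In pooled
  comparisons the class listed first is treated as positive — a
  convention, since the published table does not state one — and
  sensitivity is its true-positive rate. The analysis unit is pooled
  pixels per stage (consistent with the group statistics);
  `roc_unit = "animal_means"` switches to per-animal means. Because the
  cutoff-selection rule of the published table is unstated, empirical
  cutoffs may differ from it by a few G-values.
* **Dunnett comparisons** use per-animal mean G-values, never pixels
  (pixels within an animal are pseudo-replicates). Adjusted p-values and
  critical values come from seeded Monte-Carlo sampling of the joint null
  of `max|t|` under the balanced-correlation structure (default 10⁵
  draws), which is simple, reproducible and testable; with one comparison
  it reduces to the pooled two-sample t-test, and it agrees with
  multivariate-t quadrature to Monte-Carlo error. The reference group is a
  parameter, defaulting to Control.

## Validation problem sizes

The test suite validates estimator consistency at the study's own cohort
sizes (10/11/15/14 animals × 200 px, 3-standard-error tolerances), SD
recovery over 100 replicate lines, slope recovery over 120–200 replicate
animals (the mean fitted Control slope must sit within ±0.01 of 0.03),
empirical-vs-closed-form AUC agreement on 100 animals per class (2 × 10⁴
pixels, chosen so Monte-Carlo noise is well below the ±0.01 check), the
AUC ≡ U property on 1000 random tied instances, and the familywise type-I
error of the Dunnett procedure at α = 0.05 over 2000 simulated null
datasets (±0.02).

## Known limitations

Synthetic cohorts validate the pipeline's statistics, not device physics;
the generator's independence assumption understates profile concordance;
Youden cutoffs are one defensible choice among several; the human
calibration rests on a single patient's four sites and supports no
between-subject inference. Deep-tissue (NIR) imaging, histology image
analysis and longitudinal modelling are out of scope.
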