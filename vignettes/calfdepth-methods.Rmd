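---
title: "Depth-image morphometrics and body-weight prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-image morphometrics and body-weight prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfdepth)
```

## The problem

Weighing pre-weaned dairy calves on a scale is slow, stressful for the
animal, and consequently rare on commercial farms. A depth camera mounted
above the milk feeder, looking straight down at the calf's back, offers a
contact-free alternative: the dorsal surface can be segmented from each
frame, simple morphometrics (width, length, contour area, average height,
volume) extracted from the depth map, and body weight (BW) predicted from
those metrics. `calfdepth` implements that full analysis chain — rule-based
segmentation, metric extraction, mask evaluation, correlation-structure
analysis, and two BW-prediction protocols — together with a synthetic-data
module that emulates the recording conditions, because the underlying farm
recordings are not publicly distributable.

The emulated geometry is fixed throughout: 1280 × 720 px frames, camera
1.51 m (1510 mm) above the floor, Holstein calves aged 21–69 days with a
population mean BW near 147 lb (SD ≈ 26 lb).

## Rule-based segmentation

The segmenter works on the colorized depth render:

1. **Hue extraction.** The RGB render is converted to HSV and the hue
   channel taken on the 0–179 half-degree scale (the scale on which the
   default threshold below is meaningful).
2. **Binary threshold at 60.** Pixels with hue strictly above 60 become
   foreground; equality goes to background. On this scale the floor
   colorizes well below 60 and the calf's elevated back well above it.
3. **Morphological cleanup.** Closing with a 5 px disc plus flood-fill
   hole removal makes detected objects solid; opening with a 5 px disc
   removes specks and splits barely-touching objects. The operator kernel
   sizes are package defaults (5 px) — the method itself only prescribes
   "filling" and "opening", not kernel geometry.
4. **Candidate selection.** Connected components are filtered in a fixed
   order: (a) template shape match, (b) filled area within
   80,000–200,000 px, (c) both bounding-box sides within 300–900 px.
   Among survivors the largest area wins (one calf is expected per
   frame). The first filter that eliminates every candidate is recorded
   as the failure status — failure is a first-class outcome, mirroring
   field conditions where roughly 40% of automatically collected frames
   defeat the rule-based method.

The **shape score** is the I1 moment-matching statistic: the seven Hu
invariants of the filled candidate region and of the template region are
log-scaled (`m = sign(h) · log10 |h|`) and compared as
`sum(|1/m_A − 1/m_B|)`. It is 0 for identical shapes and invariant to
translation, rotation and scale; candidates above 0.8 are rejected.
Invariants with magnitude below 1e−5 are skipped (they are numerically
meaningless after log-scaling); a zero-area candidate scores `Inf`.

Design choices worth flagging:

* Threshold equality maps to background ("strictly above" reading).
* The filter order shape → area → bbox follows the method's narration;
  diagnostics retain every candidate's measurements regardless.
* The pipeline contains no randomness; segmentation is bit-reproducible.

## Body metrics

Per-pixel height above the floor is `camera_height − depth`, clipped at 0.
Missing depth readings ("black pixels", stored as depth 0) inside the
contour are imputed with the mean height of the valid in-contour pixels —
imputation therefore preserves the in-mask mean. Volume is the sum of
heights over the filled contour (units mm·px²), average height is
volume/area, and width/length are the axis-aligned bounding-box sides
with width canonically the shorter side. The identity
`volume = avg_height × area` holds by construction and is asserted in the
tests. A frame whose in-contour depth is entirely missing is unusable and
raises an error.

Since each calf yields many frames per visit, downstream analyses use the
per-(calf, date) **median** of each metric (even group sizes take the mean
of the two middle values).

## Mask evaluation and method comparison

IoU, Dice and pixel accuracy are computed per frame against ground-truth
masks rasterized from polygon annotations (interior plus boundary pixels,
union over polygons). Two conventions: a pair of empty masks scores 1
(perfect agreement is never penalized), and failed segmentations are
excluded from metric means but reported through the success rate.
`compare_methods()` runs a one-way ANOVA per metric, reports
η² = SS_between/SS_total, Tukey HSD letters, and a Bonferroni-adjusted p
whose family size is a **required argument** — published analyses of this
kind are not consistent about the family definition, so the package never
guesses it.

## Correlation structure across age

Pearson matrices over the five metrics plus BW are computed per age
quartile. Quartile edges use the nearest-rank convention (cut values at
ranks ⌈n/4⌉, ⌈n/2⌉, ⌈3n/4⌉) with ties going to the lower group; the
convention is stated because unequal-width age groups make the choice
visible. Pairs of group matrices are compared with a **Mantel test**:
Pearson correlation of upper-triangle entries, one-sided significance via
simultaneous row/column permutation of one matrix,
`p = (1 + #{r_perm ≥ r_obs}) / (1 + n_perm)`. The default 999 permutations
make p = 0.001 the smallest attainable value. One-sided testing matches
the scientific question (are the structures *similar*?).

## Body-weight prediction

**Single time point.** Calf-grouped 5-fold cross-validation: folds
partition *calves*, never rows, so no animal contributes to both train and
test. The protocol repeats 100 times with reshuffled folds; each
repetition pools the five folds' test predictions before computing R²,
MSE, RMSE, MAE and MAPE (pooling is variance-stabler than fold-averaging
at 4 test calves per fold). R² uses the test-set mean baseline. Models:
ordinary least squares on the six predictors (age + five metrics), and
gradient-boosted trees (xgboost) with a randomized search over learning
rate [0.01, 0.9], trees [50, 10,000] and L1/L2 regularization [0, 1].
Hyperparameter selection uses 3-fold CV *within the training split* (RMSE
objective), so the search never sees test animals.

**Multiple time points.** Each calf's series is split chronologically —
the earliest X% of visits (X ∈ {90, 80, 70, 60, 50}, floor rule clamped to
[1, n−1]) trains, the rest tests; calves with fewer than five visits are
excluded. Before every split one random visit of one random calf is
removed, emulating missing data; the experiment repeats (100× in the full
protocol) to give spread to the metrics. Models: the two above plus a
**random-intercept linear mixed model** (lme4, REML) — six fixed effects
plus `(1 | calf_id)`, literally a random intercept and nothing more. Test
rows of calves seen in training use the calf's predicted intercept;
unseen calves fall back to fixed effects. Per split, models are compared
by ANOVA with Tukey letters, Bonferroni family 3 (the three-model
comparison), and η².

On herds with strong between-calf heterogeneity the mixed model dominates
both pooled models, because it is the only one that can carry a calf's
individual level forward in time; the boosted trees, which treat visits
as exchangeable rows, degrade fastest as the training fraction shrinks.
The package's tests reproduce this ordering directionally; the published
absolute performance numbers depend on the real farm images and are out
of reach by construction.

## The synthetic-data generator

**Scenes.** The calf is a body ellipse (defaults 620 × 300 px) plus a head
ellipse, with a flattened-dome height profile
`height = peak · (1 − d⁸)^(1/2)` (peak 420 mm) so the back is nearly flat
and falls off steeply at the flanks. The floor sits at camera height with
Gaussian noise (SD 4 mm); calf depth noise is 2 mm. Color derives from
depth through a monotone ramp `hue = min(170, 30 + 0.6 · height_mm)`:
the floor colorizes near hue 30, the calf's back far above 60, and the
hue-60 crossing occurs at 50 mm height, which keeps the mask/threshold
disagreement to a thin rim (clean-scene IoU ≈ 0.996). The ramp is a
package choice — the original colorization is not specified anywhere — and
is documented precisely because the threshold of 60 only means something
relative to it. Ground-truth masks are captured *before* defect
injection, so truth is defect-free by construction. Defects emulate the
two field failure modes: overexposure of white coat patches (contiguous
circular patches of missing depth, radius 45 px, up to a requested
fraction of calf pixels — patches, not salt noise, because closing would
trivially repair isolated pixels) and vertical fence bars rendered 350 mm
above the floor.

**Herds.** BW follows a linear random-coefficients growth model
`BW_ij = (β₀ + u0_i) + (β₁ + u1_i)·age_ij + ε_ij` with β₀ = 85 lb,
β₁ = 1.4 lb/day, SD(u0) = 12 lb, SD(u1) = 0.25 lb/day, SD(ε) = 5 lb.
Visit ages run on a 3–4 day cadence from a calf-specific entry age chosen
so the visit-age distribution centres on 45 days; with ages 21–69 days
this calibration puts the population mean near 147 lb and the overall SD
near 26 lb — the trial regime the analysis assumes. The five metrics are
affine in true BW with multiplicative Gaussian noise whose level is
derived from a target metric–BW correlation (defaults 0.93 for contour
area, 0.91 for volume, 0.85–0.88 for the rest), so the default herd
reproduces the strong-correlation regime. All link settings are exposed.

What the generator deliberately does **not** emulate: real coat-pattern
texture, posture variation (raised heads, leaning against the fence),
perspective distortion, or sensor-specific noise spectra. Passing tests
therefore demonstrate that the *analysis chain* is correct and that its
statistical behaviour matches the published regime directionally; they do
not certify performance on real farm imagery.

A second generator, `simulate_lmm_table()`, draws the six predictors
exogenously and builds BW directly from the random-intercept model; it is
the ground truth for parameter-recovery checks (with 50 calves × 10
visits, σ_b = 10 lb, σ_e = 3 lb, the fitted age coefficient lands within
10% and both variance components within 30% of truth across seeds).

## Numerical and protocol choices

* **Coordinates** are (row, col), 0-based at I/O boundaries; masks are
  {0,1}; depth is millimetres with 0 = missing; depth CSVs are one image
  row per line, comma-separated, no header.
* **Polygon fill** is boundary-inclusive: strict interior via an even-odd
  test plus explicit edge rasterization. A convex polygon's pixel count
  differs from its analytic area by at most its perimeter.
* **Desk vs full profile.** The reference protocol (1000 search
  candidates, up to 10,000 trees, 100 repetitions) is available but the
  package defaults to a desk profile — 10 candidates, ≤ 300 trees, 5–20
  repetitions — sized so the repeated experiments run end to end on a
  single workstation core in minutes. The reported experiments in the
  test suite and acceptance script use the desk profile; all protocol
  constants remain configurable.
* **Seeding.** Every stochastic step takes an explicit seed; repetition
  seeds derive from the master seed by a fixed counter scheme, so whole
  experiments are exactly reproducible and the caller's RNG state is
  never touched.
* **Degenerate inputs.** Zero-variance columns yield flagged NA
  correlations, not 0; a constant training response is a fitting error;
  singular mixed-model fits are flagged warnings; identical model groups
  yield η² = 0 with the ANOVA marked unavailable.

## Known limitations

* The synthetic scene is a smooth two-ellipse animal; shape-score margins
  against real calf silhouettes will differ, and the 0.8 cut is carried
  as configuration, not re-validated here.
* The defect model produces failure *rates* that depend on the injected
  severity; only the direction (clean ≫ defective) is meaningful.
* The mixed model carries a random intercept only; growth-rate
  heterogeneity enters the generator but is absorbed by the residual in
  the fitted model, which is the intended, deliberately simple protocol.
* MAPE requires strictly positive observed weights (always true here).
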