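---
title: "Topological strain motifs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological strain motifs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainTDA)
```

## Overview

`strainTDA` turns segmental speckle-tracking strain data into
fixed-length topological feature vectors and uses them to separate
constrictive pericarditis (CP), restrictive cardiomyopathy (RCM) and
normal (NL) subjects. This vignette is the package's own account of the
science: the model at each stage, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and the places where the design was genuinely open.

## From traces to motifs

### Input model

A cohort is a set of patients, each carrying up to 290 series: 49 apical
four-chamber (A4C) points × {LS, LSR} and 48 mid-ventricular short-axis
(SAX) points × {CS, CSR, RS, RSR}. Strain is in percent, strain rate in
1/s, and each series samples one cardiac cycle (times in ms are detected
by `max(time) > 1.5` and rescaled so the last sample is cycle fraction
1). The measure↔view assignment is fixed — longitudinal from A4C,
circumferential/radial from SAX — because only that split makes the
6 measures × 3 regions = 18 combinations the motif needs.

### Completeness rule

A patient enters analysis only if every required (measure, region) pair
can be formed. A series with ≥ 4 finite samples but internal NaNs is
considered repairable (the spline simply interpolates through the finite
samples); fewer than 4 finite samples makes the series unusable and
drops the patient, with the failing pair recorded. The rule is total and
idempotent, and `cohort_summary()` serialises the outcome.

### Regions

Segment indices are grouped into contiguous, near-equal thirds: SAX
1–16 / 17–32 / 33–48 (anterior septal, inferior septal, lateral) and A4C
1–16 / 17–33 / 34–49 (septum, apex, lateral; sizes 16/17/16). Vendor
conventions for point ordering vary, so the map is overridable via
config (`region_map`), with the constraint that the three regions
partition the view's full index range.

### Cycle standardisation and averaging

Each segmental series is resampled to `T = 100` uniform cycle fractions
with an interpolating cubic spline, then segments of a region are
averaged pointwise. `T = 100` is not a physiological constant — it is a
round grid that leaves the delay-embedded clouds at 96 points; it is
configurable (`resample_T`). We normalise per segment *first* and
average after, so segments sampled on different raw grids contribute on
equal footing; because spline interpolation is linear in the data, the
two orders agree whenever segments share knots (a property the tests
check numerically).

Boundary conditions: the default is the *natural* spline (zero second
derivative at the cycle ends), which avoids endpoint overshoot on a
single cycle. Note that natural end conditions cannot reproduce an
arbitrary cubic polynomial near the boundary; `bc = "fmm"` (R's default
end rule, exact for cubics) is available where that matters.

### Delay embedding

Each regional curve is mapped to the 3-dimensional point cloud
`(x_i, x_{i+2}, x_{i+4})` (embedding dimension `d = 3`, delay `τ = 2`,
both configurable but fixed by the workflow; automatic selection of
`d`/`τ` is out of scope). The cloud has `T − (d−1)τ` points; indexing is
0-based and points are ordered by start index, though every downstream
quantity is permutation-invariant.

### H0 persistence

For a Vietoris–Rips filtration on a finite cloud, dimension-0 classes
are all born at scale 0 and the finite ones die at the single-linkage
merge heights, i.e. the edge weights of a Euclidean minimum spanning
tree. `rips_h0()` therefore computes Prim's algorithm on the exact
distance matrix — no simplicial machinery is needed for H0 — and the
test suite checks exact agreement with an independent single-linkage
dendrogram on hundreds of random clouds. The single essential
(never-dying) component is dropped before imaging and flagged on the
diagram. Loops (H1) and higher homology are deliberately out of scope.

One convention deserves a flag: the filtration scale here is the
*pairwise distance* at which an edge appears, matching the convention of
the standard Rips software. Textbook pictures that grow a ball of radius
ε around each point merge components at distance/2; the two
parametrisations differ by a factor of 2 and we use the former.

### Persistence images

Each diagram is vectorised as a 1 × 50 linear persistence image: every
pair contributes an isotropic Gaussian at its (birth, persistence)
position with variance `σ² = 0.005` — the workflow names a *variance*,
so σ ≈ 0.0707 — weighted linearly `w(p) = p / p_max` so that weight
vanishes on the diagonal. With birth resolution 1 (all H0 births are 0)
the birth axis integrates out, and each pixel receives the *exact*
Gaussian mass in its persistence bin via CDF differences rather than a
centre-point evaluation; this is deterministic and robust to resolution
changes, and makes mass conservation (`Σ pixels = Σ w(p_i)` when the
bounds cover every pair) testable at 1e-6.

**Image bounds.** The bounds determine what a pixel index *means*. Two
modes exist:

* `bounds_mode = "cohort"` (default): for each (measure, region) row the
  persistence axis is fitted over that row's diagrams across the whole
  cohort (`[0, max persistence + one pixel width]`). Pixel position then
  carries the absolute persistence scale, motifs are comparable across
  patients, and the characteristic class patterns — restrictive
  physiology concentrating mass at *lower* persistence pixels because
  its low-amplitude, tightly clustered dynamics become fully connected
  at a smaller scale — are visible in class-average motifs.
* `bounds_mode = "diagram"`: each image uses its own diagram's automatic
  bounds. This normalises scale out (two clouds differing only by a
  global scale factor produce nearly identical images), which discards
  precisely the amplitude information the motif is meant to display. It
  is retained as an option for workflows that want scale-free shape
  descriptors.

We default to cohort bounds because the motif's documented
interpretation and the class-average patterns require a shared axis;
this is the package's design choice where the upstream tooling would
also fit bounds over whatever collection it is handed. The small
information flow across patients through a shared `p_max` is noted; it
uses only the maximum persistence, not labels.

### Motif assembly

The 18 images are stacked in a canonical, documented row order —
measures alphabetically (CS, CSR, LS, LSR, RS, RSR), regions within each
measure in anatomical order — giving the 18 × 50 motif and, row-major,
the 900 named features `"{measure}_{region}_px{01..50}"`. The naming
makes SHAP output directly mappable back to motif coordinates
(`motif_coordinates()`). `render_motif()` draws the heatmap with a fixed
perceptually uniform palette recorded in a JSON sidecar, so renders are
reproducible byte for byte.

## Modelling

### Feature selection

`boruta_select()` implements all-relevant shadow-feature selection: per
iteration, shuffled copies of the still-undecided features (padded to a
minimum of five shadows) join the design matrix, a random forest
(ranger, permutation importance) is fitted, and a feature scores a hit
when it beats the best shadow. Hit counts are tested against
Binomial(n, ½) two-sided with Bonferroni correction across the currently
undecided features (α = 0.05); survivors at `max_iter = 100` are
tentative. The run is a pure function of `(x, y, seed)`.

A calibration note: with many more features than samples, a handful of
noise features carry *stable* chance correlations with the labels; they
persist across iterations while shadows are re-randomised, so any
shadow-max scheme occasionally confirms a few of them. The controlled
quantity is the confirmed-noise *fraction* (observed ≈ 1–2 %, within
α = 5 % in the simulation tests), not an exact zero.

By default selection runs once on the full table before modelling,
mirroring the published workflow; `nested_selection = TRUE` refits the
selection inside every training fold instead — the statistically honest
mode when the CV estimate itself is the quantity of interest — and the
per-fold feature lists are logged so honesty is auditable.

### Classifiers

Task–model pairings follow the workflow: logistic regression for
CP-vs-RCM and CP-vs-NL, random forest for RCM-vs-NL and the multiclass
task. Logistic regression is glmnet ridge with fixed `λ = 1/n`
(equivalent to "L2 penalty, strength 1.0" in the common C = 1
convention); a single-predictor table — the GLS baseline — uses a plain
maximum-likelihood `glm`, since one predictor needs no shrinkage and
glmnet requires two columns. Random forests run as one boosting round of
500 bagged parallel trees (subsample 0.632, √p features per split,
depth ≤ 12) in xgboost; this choice gives one engine for both binary and
multiclass forests and a tree dump precise enough for exact attribution
(below). All hyperparameters are exposed and recorded.

Evaluation is stratified k-fold (default tenfold) with out-of-fold
scores pooled before computing the ROC, the Mann–Whitney AUC (identical
to the trapezoidal area; ties count ½) and the operating point. The
reported sensitivity/specificity sit at the Youden-optimal pooled
cut-point (ties broken toward sensitivity) with the threshold recorded —
the workflow never states its operating rule, and Youden is the standard
single-point summary. Multiclass sensitivity/specificity are one-vs-rest
at each class's own Youden point, macro-averaged, which resolves the
ambiguity in "average across all classes".

### Model comparison

`delong_compare()` implements the paired DeLong test via placement
values: the covariance of the paired placement vectors gives the
variance of the AUC difference and a two-sided normal p-value. Fold
assignments depend only on `(labels, k, seed)`, so the topological model
and its GLS baseline are scored on identical folds and the pairing is
exact. Degenerate zero-variance comparisons with equal AUCs (identical
scores) return p = 1 by contract. The null rejection rate is verified by
simulation (≈ 4–5 % at α = 5 %), and agreement with an independent
implementation is tested to 1e-9.

### Attribution

`shap_explain()` computes exact path-dependent TreeSHAP in compiled
double-precision code over the parsed tree ensemble, with node covers as
the background distribution. Local additivity — per sample and class,
attributions plus the per-class expected margin equal the ensemble's
margin — holds to ~1e-15, and the implementation is cross-checked
against the booster's own (float32) TreeSHAP to ~1e-7. The traversal
reproduces the booster's float32 threshold-comparison semantics exactly.
Features are ranked per class by mean absolute attribution and reported
with their motif coordinates.

## The synthetic cohort generator

Real strain tables are not distributable, so `simulate_cohort()`
generates labelled cohorts from class presets. The waveform is a C¹
raised-cosine deformation-and-recovery template: zero at both cycle
ends, signed peak (negative for LS/CS, positive for RS) of magnitude A
at the end-systolic fraction `t_es`, with a shape exponent on the
recovery limb. Strain-rate series are the *analytic* derivative of the
paired strain template (scaled by cycle length and 1/100 to 1/s), so
presets only carry amplitudes for the three strain measures.

Default presets are invented from textbook strain ranges and are
config-exposed; none claim to match any real cohort:

| class | LS (%) | RS (%) | CS (%) | regional pattern | t_es |
|-------|--------|--------|--------|------------------|------|
| NL | 20 ± 2 | 38 ± 3 | 20 ± 2 | uniform | 0.35 |
| RCM | 8 ± 2 | 16 ± 3 | 9 ± 2 | uniform (globally low) | 0.32 |
| CP | 18 ± 2 | 30 ± 3 | 18 ± 2 | lateral ×0.55, apex ×0.8 | 0.36 |

Per segment, amplitude = patient draw × regional modifier + a
heterogeneity draw (SD 1.0 %); Gaussian sample noise has SD 0.5 %
strain (0.05 1/s for rates); raw series have 55–70 samples over a
850–950 ms cycle. Each patient consumes an independent substream of the
master seed, so a patient's data is reproducible regardless of
generation order.

`regional_sparing_spec()` is a designed two-class scenario in which the
sparing class redistributes amplitude regionally with modifiers whose
segment-weighted mean is exactly 1 (16·4/3 + 17·1 + 16·2/3 = 49), making
the per-patient GLS distribution identical across classes while regional
curves differ. It exists to demonstrate — not merely assert — that the
motif captures regional signal a global mean cannot see: on it the GLS
baseline performs at chance and the motif model near AUC 1.

**What the generator does not emulate:** speckle-tracking measurement
artefacts, vendor-specific drift and inter-vendor variability,
respirophasic septal shift (a hallmark of real CP), valve-event timing
inside the cycle, arrhythmic beat-to-beat variation, or any biophysical
(finite-element/hemodynamic) coupling between segments beyond shared
patient parameters. Passing the end-to-end tests therefore demonstrates
that the pipeline is correct and can recover class structure of this
kind at realistic noise levels — it does not certify clinical
performance on real patients, whose separability is far harder (real
cohort AUCs live well below 1).

## Numerical choices and degenerate inputs

* Spline repair needs ≥ 4 finite samples; fewer is an explicit error at
  the resampler and a drop at the cohort filter.
* Clouds with < 2 points give an empty finite diagram (essential class
  only), and empty diagrams give all-zero images with fallback bounds
  (0, 1).
* MST edge weights are unique as a multiset even when the MST is not;
  deaths are reported sorted ascending.
* Pixel integration uses CDF differences; tiny negative rounding is
  clamped at 0.
* Auto bounds pad the maximum persistence by one pixel width so the
  largest pair's centre lies inside the last pixel.
* ROC thresholds run from +∞ down through the unique scores; constant
  scores give the chance diagonal and Sn + Sp = 1 at every cut.
* Binomial decisions in selection are two-sided; a feature can only be
  confirmed or rejected once, and confirmed features stay in the forest
  but are no longer shadowed.

## Problem sizes used by the tests

The shipped tests and the acceptance script run entirely on simulated
data at the study's default conditions: 50 patients per class for the
end-to-end classification checks (tenfold CV), 20 replicate selection
runs at n = 100 with 201 features, 500 DeLong null replicates, and 200
random clouds for the H0 oracle. These sizes were chosen so the whole
suite documents the method at full fidelity while remaining quick to run
on a laptop.

## Known limitations

* H0 only; loops (H1) may carry additional physiology but are untested
  here and out of scope.
* Cohort-fitted image bounds couple patients through a shared scale
  (see above); per-diagram bounds are available but change what pixel
  position means.
* The default selection-before-CV mirrors the published workflow and
  can leak selection information into CV estimates; use
  `nested_selection = TRUE` when the CV number itself is the claim.
* The GLS baseline is the mean segmental peak, an approximation to
  vendor GLS, not a vendor implementation.
* With features ≫ samples, shadow-feature selection retains a small
  fraction of stably chance-correlated noise features by construction.
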