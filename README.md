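# strainTDA

Topological motifs from segmental cardiac strain curves.

## The problem

Constrictive pericarditis (CP) and restrictive cardiomyopathy (RCM) are
rare heart-failure phenotypes that present almost identically on routine
echocardiography yet demand opposite treatments (pericardiectomy vs.
medical management). Speckle-tracking echocardiography produces rich
segmental deformation data — longitudinal, radial and circumferential
strain and strain rate at 49 apical four-chamber (A4C) and 48
mid-ventricular short-axis (SAX) myocardial points over a cardiac cycle —
but clinical practice typically collapses all of it into a single number
(global longitudinal strain, GLS). `strainTDA` instead summarises the
*shape* of the deformation pattern with persistent homology and uses the
resulting fixed-length feature vectors to classify CP, RCM and normal
(NL) subjects from small cohorts.

## The method

For each patient and each of the 18 combinations of measure
(CS, CSR, LS, LSR, RS, RSR) and wall region (three per view):

1. **Regional mean curve.** Each segmental trace is standardised to one
   cardiac cycle on a uniform grid of `T = 100` cycle fractions by cubic
   spline, then the segments of a wall region are averaged.
2. **Phase-space reconstruction.** The curve `x(t)` is delay-embedded
   into the point cloud `p_i = (x_i, x_{i+τ}, x_{i+2τ})` with `d = 3`,
   `τ = 2` (96 points).
3. **Persistent homology (H0).** For the Vietoris–Rips filtration over
   Euclidean distance, every connected component is born at scale 0 and
   the finite components die at the single-linkage merge heights — the
   edge weights of the Euclidean minimum spanning tree. The one
   essential class is dropped.
4. **Persistence image.** The diagram is mapped to birth–persistence
   coordinates and vectorised as a linear persistence image with
   resolution `[1, 50]` and Gaussian variance `σ² = 0.005`, weight
   `w(p) = p / p_max`: pixel `k` integrates the exact Gaussian mass
   `Σ_i w(p_i)·[Φ((e_{k+1}−p_i)/σ) − Φ((e_k−p_i)/σ)]` over equal
   persistence bins spanning the image bounds (fitted per
   (measure, region) across the cohort by default).
5. **Motif.** The 18 images are stacked into an 18 × 50 heatmap — the
   patient-specific motif — and flattened into 900 named features
   (`CS_ant_sept_px01` … `RSR_lat_px50`).

Modelling follows the workflow's published pairings: shadow-feature
(Boruta-style) all-relevant selection, then logistic regression for
CP-vs-RCM and CP-vs-NL, a random forest for RCM-vs-NL and the
three-class task, all under stratified tenfold cross-validation with
pooled out-of-fold ROC, AUC, and Youden-optimal sensitivity/specificity.
Each topological model is compared against a single-feature GLS logistic
baseline (mean signed peak of the 49 A4C longitudinal-strain segments)
with a paired two-sided DeLong test, and the multiclass forest is
explained with exact path-dependent TreeSHAP attributions (computed in
double precision; per-sample additivity holds to ~1e-15).

No patient data ships with the package. A synthetic cohort generator
(`simulate_cohort`) emulates class-dependent amplitude (NL ≈ 20 %
longitudinal strain, RCM ≈ 8 %, CP with lateral-wall sparing), regional
heterogeneity, end-systolic timing and additive noise, so that every
stage is testable end to end.

## Worked example

```r
library(strainTDA)

cohort <- simulate_cohort(synthetic_spec(c(CP = 15L, RCM = 15L, NL = 15L), seed = 42))
flt    <- filter_complete(cohort)          # completeness exclusion rule
flt$kept
#> <strain_cohort> 45 patients (CP 15, RCM 15, NL 15), 13050 series

motifs <- extract_motifs(flt$kept)         # curves -> clouds -> H0 -> images
motifs[["RCM001"]]
#> <strain_motif> RCM001: 18 x 50 (rows = measure_region, cols = persistence pixels)

features <- motif_feature_table(motifs)    # 45 x 900
gls      <- gls_feature(flt$kept)          # 45 x 1 baseline feature
models   <- train_strain_models(features, gls, flt$kept$labels,
                                seed = 42, k = 5,
                                boruta_args = list(max_iter = 50))
models
#> <strain_models>
#>   selection: 73/900 features confirmed
#>   CP_vs_RCM  PH AUC 1.000 vs GLS AUC 0.876 (DeLong p = 0.13)
#>   CP_vs_NL   PH AUC 1.000 vs GLS AUC 0.929 (DeLong p = 0.23)
#>   RCM_vs_NL  PH AUC 1.000 vs GLS AUC 1.000 (DeLong p = 1)
#>   multiclass PH macro AUC 1.000 vs GLS 0.724

sh <- shap_explain(models$multiclass,
                   features[, models$selected_features, drop = FALSE], top_n = 3)
sh
#> <shap_summary> 3 class(es); additivity residual 2.33e-15
#>   class rank      feature mean_abs_shap
#> 1    CP    1 CSR_lat_px42    0.06879688
#> 2    CP    2 CSR_lat_px46    0.05374974
#> 3    CP    3 CSR_lat_px28    0.05333392
```

Reading the output: the topological models separate the synthetic
classes perfectly (AUC 1.000) while the GLS baseline is weaker wherever
class differences are regional rather than global; the top SHAP features
for the CP class sit in the lateral-wall circumferential strain-rate
rows of the motif — exactly the region the CP preset spares. On a
designed "regional sparing" scenario whose classes share an identical
GLS distribution (`regional_sparing_spec()`), the GLS baseline falls to
chance while the motif model stays near AUC 1.

`render_motif()` draws the Fig.-4-style heatmap of any motif, and the
thin CLI at `inst/cli/straintda` exposes the stages as
`simulate / extract / train / explain / render` subcommands over a JSON
config.

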