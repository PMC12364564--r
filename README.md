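# spinemorph

Quantitative analysis of the shape and puncture mechanics of biological
puncture tools, built around the hemipenial spines of snakes: calcified
genital spines whose morphology ranges from needle-like to deeply hooked,
and whose ability to puncture a skin-like substrate varies just as widely.
The package is for morphologists and biomechanists who want to go from
spine geometry (2D sagittal profiles or 3D meshes) and raw
force–displacement compression traces to comparable, per-spine shape and
performance metrics — and to test how the two relate.

## What it computes

**Tool-property metrics** (`spine_metrics()` and friends), replacing manual
on-screen measurement with defined algorithms:

- *tip angle* — the wedge angle α of the tapering flanks near the apex,
  from total-least-squares lines fit to the two flanks (scale-independent
  sharpness);
- *tip radius of curvature* — the radius r of the circle best fitting the
  apex (Kasa algebraic fit + Gauss–Newton refinement), reported in mm and
  normalised by the longest-axis length;
- *structural curvature* — the arc angle θ subtended, at the center of a
  circle fit to the tool's centerline, between the tip and the last
  centerline station the circle still bisects;
- *volume* — by the divergence theorem over a watertight triangle mesh;
- *morphotype flags* — elongate / hooked / wavy / conical, with explicit,
  configurable thresholds.

**Puncture performance** (`detect_puncture()`, `performance_table()`):
puncture events are sharp force drops in a compression trace. A trial at
approach angle φ succeeds if a drop of at least
max(0.5 N, 10% of peak) completes within 0.2 mm; per spine the package
reports the *puncture range* (max − min successful angle over a 10°
serial-angle grid), the *lowest force*, and the *average force* (mean over
angles of per-angle replicate means).

**Morphospace** (`gpa()`, `shape_pca()`, `procrustes_lm()`,
`phylomorphospace()`): generalized Procrustes alignment of landmark
configurations, PCA of aligned shapes, permutation (residual-randomization)
linear models of shape on covariates, and Brownian/squared-change-parsimony
ancestral states to project a phylogeny into the morphospace.

**Shape–performance screens** (`shape_performance_screen()`): pairwise OLS
of each performance response on each shape predictor, with explicit cohort
policies (broken spines excluded by default) and a packaged transcription
of the reference per-species and per-spine tables (`load_spine_tables()`).

A synthetic-data module (`generate_spine_profile()`,
`simulate_force_trace()`, `simulate_experiment()`) generates spine outlines
around circular-arc centerlines and compression traces with embedded drops,
carrying exact ground truth for every metric, so the entire pipeline is
testable without instrument data.

## Worked example

```r
library(spinemorph)

# a hooked synthetic spine with known ground truth
gs <- generate_spine_profile(spine_gen_params(tip_angle = 45,
                                              structural_curvature = 90))
spine_metrics(gs$profile, spine_id = "demo")[, c(
  "spine_id", "tip_angle_deg", "structural_curvature_deg", "hooked")]
#>   spine_id tip_angle_deg structural_curvature_deg hooked
#> 1     demo      45.55968                 87.24653   TRUE

# the shape-performance regression on the packaged per-spine table
t2 <- load_spine_tables()$table2
shape_performance_screen(t2, response = "average_force",
                         predictors = "tip_angle_deg")[, c(
  "predictor", "slope", "r_squared", "p_value", "n")]
#>       predictor     slope r_squared    p_value  n
#> 1 tip_angle_deg 0.7404126 0.3574826 0.05203645 11
```

The measured tip angle (45.6°) and structural curvature (87.2°) recover the
generative values (45°, 90°) within the package's documented tolerances.
The regression says that over the 11 spines with force data (broken spine
excluded), each degree of tip angle adds about 0.74 N to the average
puncture force, a marginally non-significant trend (p ≈ 0.052) — blunter
spines need more force.

## Vignette

`vignettes/spine-puncture-analysis.Rmd` documents the models, the
measurement algorithms and their parameters, the synthetic-data
assumptions, and known limitations.
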