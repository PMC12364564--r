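---
title: "Shape metrics and puncture mechanics of genital spines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape metrics and puncture mechanics of genital spines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

## The problem

Snake hemipenes carry hundreds to thousands of calcified spines whose
shapes span needle-like cones, broad blunt cones and deeply hooked blades.
Whether and how these spines puncture the vaginal wall depends on their
geometry: how sharp the tip is, how curved the whole tool is, and at what
approach angles puncture remains possible. `spinemorph` implements the
full quantitative chain for this question: defined, reproducible shape
metrics; event extraction from compression tests; landmark morphospace
analysis; and the pairwise regressions connecting shape to performance.

## Tool-property metrics

All 2D metrics operate on a `spine_profile`: a simple closed polygon in
the spine's local sagittal plane (the plane in which test rotations
occur), with a designated apex vertex.

**Centerline.** Cross-section midpoints are traced from the apex to the
base. The slice direction is estimated locally from the boundary tangents
at the two slice crossings, weighted so their cross-axis components
cancel; for symmetric offsets of a straight or circular-arc centerline
this estimator is exact, and unlike secant-based direction updates it does
not oscillate in tapering regions. A fixed-point refinement pass then
re-slices the outline perpendicular to wide-window chord tangents of the
traced polyline. For circular arcs the chord between points at s ± w/2 is
exactly parallel to the tangent at s, so wide windows cost no accuracy on
arcs while suppressing short-wavelength error; a window proportional to
the local width (4 half-widths) keeps the update contractive. Slices that
cross an edge nearly perpendicular to the axis have hit the flat base and
are discarded; the base endpoint is rebuilt as the exit of the axis
through the boundary.

**Tip angle** (degrees). Total-least-squares lines are fit to the two
flank point sets within a boundary-arclength window of the apex
(`flank_window`, default 0.15 of the longest-axis length), excluding the
rounded cap (`cap_exclusion`, default 0.05); the angle between the
oriented lines is returned. The windows are the main tunables; the
defaults sit in the regime where the sweep in the test suite shows the
value stable to about ±3° across windows 0.10–0.20, provided the flanks
are straight through the window.

**Tip radius of curvature** (mm, and normalised by the longest-axis
length). A circle is fit (Kasa algebraic fit, then Gauss–Newton
refinement of radial residuals) to the outline points within `cap_window`
(default 0.05) of the apex. When the window reaches past the rounded cap
onto straight flanks no circle describes the points; the fit is flagged
unreliable when the root-mean-square residual exceeds 2% of the radius,
and by default the window shrinks by 30% steps until the fit becomes
reliable. The normalised value is the comparable quantity across tools
scaled to a common length; note that scaling tools to one length makes
this measure shape-, not size-, dependent.

**Structural curvature** (degrees). A circle is fit to the centerline and
the reported value is the arc angle between the tip and the last station
the circle still "bisects" the tool, operationalised as: every included
station lies within `deviation_tol` (default 0.25) of its local
half-width from the fitted circle, with a floor of 10% of the maximum
half-width so the vanishing width at the apex cannot veto the fit. The
included run is found by searching downward from the full centerline,
because large fits are well conditioned while small tip-anchored fits
overfit residual jitter; stations within 3% arclength of the apex (the
rounded cap, which carries no curvature information) are excluded.
Centerlines whose fitted radius exceeds 1000 times the length are
reported as 0° (straight).

**Volume** (mm³) is the divergence-theorem sum over an oriented,
watertight triangle mesh; open edges are a hard error.

**Morphotype.** Four binary flags with explicit thresholds: elongate
(aspect ratio < 0.5, i.e. short spines are those wider than half their
length), hooked (structural curvature ≥ 60°), wavy (at least two sign
changes of centerline turning above 1° per station), conical
(out-of-plane/in-plane width ratio ≥ 0.8). All thresholds are arguments
and are recorded in the result.

## Puncture performance

A puncture event is a sharp drop in the force–displacement curve. The
detector median-smooths the force (window 5 samples), scans for local
maxima, and reports an event when the smoothed force falls by at least
max(0.5 N, 10% of the peak) within 0.2 mm of displacement — and stays
down: the median of the smoothed force just after the trough must also
sit a full threshold below the peak, which removes transient noise dips
that genuine material failure never produces. The reported peak force is
the unsmoothed maximum within the smoothing window of the detected peak.
These four constants are the package defaults, exposed as arguments and
validated in the test suite against the trace simulator (100%
sensitivity, 0% false positives, peak error within 3 noise standard
deviations, at 0.2 N noise).

Per-spine summaries follow the serial-angle protocol (10° increments,
three replicates per tool–angle combination): an angle succeeds when any
replicate punctures (a majority rule is available; replicate disagreement
is flagged in the output), the puncture range is max − min successful
angle (0 when at most one angle succeeds, matching the convention that a
never-puncturing tool has range 0 with missing forces), the lowest force
is the minimum over all successful replicates, and the average force is
the mean over successful angles of per-angle replicate means — per-angle
averages first, then across angles. Whether per-angle averages should
include failed replicates is not decidable from the protocol; the package
averages successful replicates only and flags angles where replicates
disagreed. Broken tools are excluded from downstream statistics via a
`broken` flag but retained in outputs.

## Morphospace

`gpa()` is standard generalized Procrustes analysis: center, scale each
configuration to unit centroid size, rotate to the consensus by the
optimal (SVD) rotation, update the consensus, iterate to a 1e-10
root-mean-square tolerance (at most 100 iterations). Rotations are proper
by default — reflections are excluded because chirality of bilateral
structures is biologically meaningful — with `allow_reflection` to opt
out. `shape_pca()` takes the eigenstructure of the vectorised aligned
coordinates; each axis is oriented so its largest-magnitude loading is
positive, making score signs platform independent.

`procrustes_lm()` regresses vectorised aligned shape on one covariate and
evaluates F = (SS_eff/df_eff)/(SS_res/df_res) by residual randomization
under the reduced (intercept-only) model, the observed case included in
the null count, so p ≥ 1/(permutations + 1) and p-values are
bit-reproducible given the seed. The permutation count (default 999) and
sum-of-squares conventions are declared here rather than inherited from
any particular implementation.

`phylomorphospace()` places internal tree nodes into the score space by
weighted squared-change parsimony — minimising Σ (change)²/branch length —
which coincides with maximum-likelihood Brownian ancestral states; the
linear system is solved exactly. Zero-length branches receive
1e-8 × tree height to keep the weights finite.

## Shape–performance regressions

`shape_performance_screen()` runs one ordinary least-squares model per
predictor (two-sided t on the slope, n − 2 degrees of freedom) with
listwise deletion, and logs the exact cohort per model. The default
cohort excludes tools flagged broken; never-puncturing tools stay in
puncture-range models (range 0) and drop out of force models through
their missing forces. No multiple-testing correction is applied to the
primary p-values — the screen reproduces marginal pairwise models — but a
Benjamini–Hochberg column is emitted alongside. On the packaged per-spine
reference table this cohort yields the marginal tip-angle effect on
average puncture force (p ≈ 0.052, n = 11); the alternative cohort
including the broken tool gives p ≈ 0.014, so the cohort choice is
material and is therefore logged.

## The synthetic-data module

The generator exists so every stage has exact ground truth. A synthetic
spine is a tapering outline swept along a circular-arc centerline: apex
wedge of the requested tip angle, an exact circular cap of the requested
tip radius, half-width saturating at half the base width, the physical
centerline subtending exactly the requested structural curvature, and the
centerline length solved by root finding so the finished outline's
longest axis equals the requested length (so cap radius and arc angle are
exact in final units). The default length is 3.22 (the common scaled tool
length used for printed test specimens) and the default base width,
max(0.12, 0.35 sin(α/2)) × length, keeps the flanks straight through the
tip-angle window while keeping the tool slender enough for a well-defined
centerline. Meshes revolve elliptical cross-sections (out-of-plane axis
scaled by `lateral_compression`) along the centerline and close with apex
and base fans.

Simulated traces rise as F ∝ d^p with p = 1.5 by default (a Hertz-like
convex ramp; any convex ramp suffices for drop detection and the exponent
is exposed), drop by `drop_fraction` (default 0.4) within one sample at
the puncture displacement, then resume rising; Gaussian noise (default
0.2 N) is seeded. The crosshead rate (10 mm/min) and travel limit
(5–15 mm) are carried as metadata; no contact mechanics is simulated, and
substrate/material moduli (skin-like substrate ≈ 1 MPa, printed resin
2.8 GPa) are treated as constants of the experimental design, not model
inputs.

`simulate_experiment()` makes success deterministic: a trial punctures
iff |angle| ≤ the spine's maximum puncture angle, which grows linearly
with structural curvature (default 5° + 0.3°/°), while the required force
grows linearly with tip angle (2 N + 0.5 N/°) and with |angle|
(0.3 N/°). The coefficients encode the qualitative links the simulator is
meant to emulate — curved tools puncture over wider ranges, blunter tools
need more force — with magnitudes chosen so forces span roughly 3–50 N
over tip angles 13–90°, the observed ranges. Success is contiguous in
|angle| by construction; the simulator has no mode for gaps in the
success profile, since serial testing protocols stop at the first failed
angle.

What the simulator does *not* emulate: real traces' machine compliance
and seating transients, multiple micro-failure events before full
puncture, tool fracture (breakage is a manual flag, not a simulated
event), and any dependence of performance on lateral compression or
waviness. Passing tests therefore demonstrate the correctness of the
algorithms on idealised geometry and traces, not robustness to every
instrument artefact.

## Numerical choices and problem sizes

- Circle fits: Kasa algebraic seed (exact on noiseless circles, stable on
  shallow arcs) + Gauss–Newton on radial residuals, 50 iterations,
  relative tolerance 1e-12; collinear inputs are an error.
- Apex identification: the designated tip vertex; for generated profiles
  it is the cap midpoint, and ties in external data are broken by the
  smallest index.
- Profiles live with the tip toward −y at 0°; trial angles are rotations
  in this plane. All metrics are rigid-motion invariant (verified to
  1e-6) so the convention only matters for plotting.
- The test suite and the acceptance script use desk-scale sizes chosen to
  exercise the guarantees at comfortable margins: a 6 × 6 factorial sweep
  of tip angle × curvature at 512-vertex resolution, 1000 + 1000 seeded
  traces for detector calibration, 200 null datasets × 999 permutations
  for the shape-model calibration, and 200 simulated 20-spine experiments
  for sign recovery.

## Known limitations

- The centerline tracer assumes a single, tube-like body; profiles whose
  cross-sections are multiply connected along the axis are rejected, and
  very squat shapes (width comparable to length) bent into strong hooks
  have no well-defined centerline to recover.
- Tip-angle windows assume locally straight flanks; tools whose flanks
  curve within 15% of the apex need narrower windows.
- The structural-curvature stopping rule makes a visual judgement
  ("where the circle stops bisecting the tool") reproducible, but its
  tolerance is a modelling choice; values are comparable only at a fixed
  tolerance.
- The normalisation of published tip-radius values is treated as
  length-normalised throughout; absolute radii in mm are also reported so
  either convention can be recovered.
- Landmark correspondence is taken as given; the farthest-point sampler
  is plumbing for desk-scale tests, not a substitute for automated
  correspondence methods.
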