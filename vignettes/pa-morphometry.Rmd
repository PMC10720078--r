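---
title: "Central pulmonary artery morphometry: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Central pulmonary artery morphometry: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamorph)
```

## The problem

Pulmonary hypertension (PH) is defined by a mean pulmonary arterial pressure
(mPAP) above 20 mmHg at rest, measured invasively by right heart
catheterization (RHC). CT pulmonary angiography (CTPA) offers non-invasive
surrogates: the diameter (D, mm), cross-sectional area (A, mm²) and volume
(V, mm³) of the main, right and left pulmonary artery (MPA, RPA, LPA). The
clinical hypothesis behind this package is that the 3D volume of the central
arteries carries more diagnostic information about PH than a 1D diameter
measured on a single slice.

`pamorph` implements the full measurement chain — segmentation → centerline →
cross-sectional areas → volume and diameter — together with the downstream
statistics (group comparison, correlation, ROC/Youden, DeLong AUC comparison,
decision-curve analysis, forward stepwise pressure prediction), and two
synthetic data generators that make the chain testable without clinical
data: CT-like vessel phantoms with exact analytic ground truth, and a
two-group patient cohort generator.

## The measurement model

**Segmentation.** The vessel lumen is the set of voxels inside the
Hounsfield window `[-200, 500]` HU (bounds inclusive) that are
26-connected to a seed placed in the MPA. The window picks up
contrast-enhanced blood (a few hundred HU) while excluding aerated lung
(≈ −850 HU) and dense bone (> 500 HU). "Region growing" is realized as
connected-component selection inside the window, which reproduces its
practical effect — discarding scattered vessels not connected to the seed;
an optional seed ± deviation intensity mode is provided. Manual cleanup by a
radiologist is emulated only as an axis-aligned ROI crop.

**Centerline.** The mask is reduced to a one-voxel-wide curve skeleton by
topology-preserving 3D thinning: voxels are visited in increasing
distance-transform order (so erosion proceeds from the surface inward) in six
directional subfields per sweep (so opposite sides erode evenly), and a voxel
is deleted only when it is *simple* in the digital-topology sense
(one 26-connected foreground component in its 26-neighborhood and one
6-connected background component in its 18-neighborhood touching a face) and
not a curve endpoint. Short leaf branches (< 5 mm) are pruned, junction
clusters connected by short internal paths are merged, and the branch passing
through the user seed (or the longest) becomes the trunk; the two longest
branches at its junction become the children, named so that `child_1` (the
RPA analog) lies on the smaller-x side in LPS orientation.

Each raw voxel path is then smoothed by a penalized cubic spline per
coordinate against cumulative chordlength. The dimensionless
`smoothing_factor` in `[0, 1]` maps to the spline penalty as
`lambda = 1e-4 * f / (1 - f)` on the normalized abscissa: factor 0
interpolates, factor 1 collapses to the least-squares line, and the default
0.5 (the conventional setting of clinical centerline tools) gives
`lambda = 1e-4`, enough to suppress single-voxel staircase jitter without
flattening vessel-scale curvature. The smoothed curve is resampled at
arclength-uniform control points (default 1 mm; the terminal remainder is
kept so the curve reaches the vessel end, with the last interval stretched
or shortened within ±20 %).

Three refinements correct systematic artifacts of voxel skeletons, and are
on by default:

- *endpoint extension*: thinning retracts free tube ends by roughly one
  radius; endpoints are extended along the end tangent (estimated from a
  15-point window) until the centerline exits the mask, trimmed by half a
  voxel for the lookup bleed;
- *sectionwise recentering*: each control point is moved to the centroid of
  its perpendicular lumen section (two passes, movement capped at 2 control
  spacings per pass, 3 spacings at each end frozen), which removes the
  off-axis drift skeletons show near junctions;
- *windowed secant tangents*: the tangent at arclength *s* is the direction
  between the curve points at *s* ± 4 mm. Sub-voxel residual wiggle barely
  moves positions but wrecks pointwise derivatives (a 0.5 mm wiggle of 8 mm
  period tilts pointwise tangents by ~20°, which inflates a cross-section by
  1/cos of the tilt); the secant is stable, and its bias is negligible for
  vessel-scale curvature radii.

**Cross-sections, volume, diameter.** The cross-sectional area at a control
point is measured on a square plane grid (half-width 30 mm, step 0.25 mm)
orthogonal to the tangent: the mask is sampled (nearest-neighbor for a
binary mask, trilinear for a fractional one), the 8-connected in-plane
region containing the center sample is kept, and the area is the sample
count times the step squared. Volume is `V = sum A(s_i) * ds_i` with `ds_i`
the local control spacing (terminal points get their full adjacent
interval), which at the conventional 1 mm control spacing is exactly the
plain sum of per-slice areas; the profile `extent` bookkeeping includes the
implied half-slab beyond each terminal point so integrals compare cleanly
against closed forms. The 1D diameter follows the radiological convention:
an axial maximum intensity projection over a 10 mm slab centered 15 mm from
the bifurcation along the artery, on which the in-lumen chord through the
measurement point, perpendicular to the branch's in-plane axis, is measured
with sub-pixel boundary interpolation. Eleven chords spread over the slab
footprint are averaged, because a single chord carries about half a voxel of
projected-edge quantization noise. The MPA ends at the bifurcation, so its
measurement point is taken 15 mm *proximal* to the bifurcation, mirroring
the "15 mm distal" rule used for the RPA/LPA; per-branch exclusion margins
(default 5 mm, roughly one branch radius) keep the pulmonary valve and the
immediate bifurcation out of every profile.

**Junction handling.** Near the bifurcation the three lumens merge and a
section plane through one branch also cuts the others. Two measures keep the
per-artery quantities well defined. First, the bifurcation itself is
re-estimated as the total-least-squares intersection of the three branch
axes (each fit on a clear segment away from the junction); the raw skeleton
junction sits 2–3 mm inside the trunk, which would shift every offset-based
measurement. Second, section samples are partitioned between branches by a
radius-normalized nearest-centerline rule: a sample counts for the measured
branch unless it is both farther than one local radius from that branch's
centerline and closer (normalized, with a 0.1 hysteresis favouring the
measured branch) to a competitor branch. Samples within one radius of the
measured branch always belong to its own tube, so a branch keeps its full
section through the overlap zone; samples beyond it that belong to the
neighboring lumen are excluded instead of leaking into the area through the
in-plane connection (unhandled, that leak inflates a child-branch area near
the bifurcation by 40–60 %).

## Synthetic phantoms

`phantom_spec()`/`rasterize_phantom()` build CT-like volumes of circular
tubes — straight segments, constant-curvature arcs (so arclength, tangents
and volume are closed-form) and polylines — with a linear radius taper if
wanted. Voxels are classified by their 8 corners plus center; mixed voxels
get a 3×3×3 supersampled in-voxel lumen fraction, and HU is linear in that
fraction between the background (default −850 HU, lung-like) and the lumen
(default 350 HU, inside the segmentation window). Gaussian HU noise is added
last; the analytic truth (centerline, tangents, `pi r(s)^2` areas,
closed-form volumes, bifurcation point) is computed from the tube parameters
and never touches the raster. `make_pa_tree_spec()` arranges an MPA-like
trunk (radius 18 mm, the scale of a dilated main pulmonary artery) with two
arc children (12 mm) leaving at ±45°.

What the phantoms deliberately do **not** emulate: cardiac/respiratory
motion, beam hardening and streak artifacts, contrast timing gradients,
non-circular (elliptical or dissected) lumina, wall thickening, and
neighboring mediastinal structures other than an optional attenuation slab.
Passing the phantom suite therefore demonstrates geometric correctness of
the measurement chain at CT-like resolution — not robustness to every
clinical artifact.

A note on voxelization: the union of three tubes can contain *sub-voxel
tunnels* near the junction creases after thresholding. Homotopic thinning
faithfully preserves such tunnels as skeleton loops, so `skeletonize()`
applies one morphological closing pass before thinning (the measurement mask
is untouched). Thinning topology was verified on a ball (collapses to a
point) and a solid torus (one loop survives).

## The synthetic cohort

`generate_cohort()` emulates a 59-patient two-group study (18 non-PH / 41
PH). mPAP drives everything: the non-PH group follows a lognormal matched to
the published median/IQR (18, 16–19 mmHg), truncated at the 20 mmHg
diagnostic boundary; the PH group follows a normal (mean 26, SD from the
20–35 IQR) truncated above 20 mmHg — so the strict label rule
`PH iff mPAP > 20` is consistent with the draws by construction. SPAP and
DPAP are linked linearly to mPAP within each group (within-group correlation
0.9), with order-violating draws resampled and finally clamped; the
resample/clamp shifts the PH DPAP mean slightly below its configured value,
a known and accepted distortion. Each of the nine CT measurements is
`alpha_g + beta_g * mPAP + eps` with group-specific coefficients solved
analytically against the *truncated* group mPAP moments, so per-group
means/SDs match the configured (published) values exactly in expectation,
and with the within-group correlation solved so the *pooled* correlation
hits the configured target (default 0.744 for V_MPA vs mPAP; infeasible
targets raise an error). Values published as median (IQR) are converted once
to mean = median, SD = IQR/1.349. Correlation targets for the remaining
measurements are chosen inside the published per-artery ranges
(0.586–0.752 MPA, 0.527–0.640 RPA, 0.302–0.495 LPA) preserving the reported
ordering (3D > 2D > 1D for MPA/RPA, reversed for LPA). Limitations: the
conditional-Gaussian construction can produce physically impossible negative
values in the strongly skewed non-PH V_RPA tail, and only the pooled (not
the per-pressure-per-group) correlation structure is controlled.

## Statistical conventions

- Normality gating by Shapiro–Wilk at alpha = 0.05 (the study-wide level)
  selects Student t (pooled variance) vs Wilcoxon rank-sum, and Pearson vs
  Spearman correlation.
- 2×2 tables: Pearson chi-square *without* continuity correction when all
  expected counts are ≥ 5 — this reproduces the published statistics
  (24.642, 9.560, 1.282) to the printed precision — otherwise Fisher's exact
  test with the two-sided point-probability rule.
- ROC: Mann–Whitney pair-counting AUC (ties ½); the Youden-optimal cutoff is
  an *observed* score value with ties broken toward the lower cutoff (higher
  sensitivity, the screening intent); positivity is `score >= cutoff`;
  the 95 % CI uses the DeLong variance. Accuracy is computed as
  (TP + TN)/N; the corresponding published column is internally inconsistent
  with its own sensitivity/specificity and class split, so those cells are
  not reproduced.
- DeLong comparison of paired AUCs via structural components; a
  rank-identical pair returns Z = 0, p = 1 exactly.
- Decision curves calibrate scores to probabilities with a univariable
  logistic fit (on perfect separation: rank-preserving min-max rescaling
  with a warning); net benefit is `TP/N - (FP/N) pt/(1-pt)` on a 0.01–0.99
  grid.
- Stepwise pressure models are forward-only with p-to-enter 0.05 on the
  partial F; `pa_pressure_models()` ships the published equations
  (`mPAP = 8.178 + 0.0006 V_MPA`, `DPAP = 1.418 + 0.0005 V_MPA`,
  `SPAP = -11.137 + 0.0006 V_RPA + 1.259 D_MPA`) as fixture models for
  `predict_pressure()`.

## Numerical choices and degenerate inputs

- Voxel indices are 0-based with the voxel-center world convention; world
  units are always mm; the canonical in-memory orientation is axial LPS.
  Index rounding uses half-up rounding (`floor(x + 0.5)`) rather than R's
  half-to-even `round()`, because half-up commutes with integer shifts and
  keeps every lookup translation-equivariant.
- HU window bounds are inclusive (the conventional reading of a min/max
  threshold).
- All internal geometric tolerances scale with the configured distances
  (control spacing, measurement offset), so the whole pipeline is
  equivariant under similarity transforms: scaling a phantom *and its grid*
  and all mm-valued settings by a factor scales D, A and V by the 1st, 2nd
  and 3rd power to within ~0.2 %. With a *fixed* grid, voxel quantization
  breaks exact similarity at the 1–2 % level for volumes (window endpoints
  move by ±1 voxel on ~45 mm extents); that is a resolution limit, not an
  algorithmic one.
- Degenerate inputs have defined behavior: empty tube lists, non-positive
  radii or spacings, out-of-window seeds, single-class labels, constant
  vectors, margins longer than a branch and ROIs that miss the grid all
  raise errors (an ROI miss warns and returns an empty mask); a blob too
  small to have a curve skeleton yields a trivially short path; a mask
  without a junction yields a single-branch tree with MPA fields only.

## Problem sizes used by the test suite

The tests exercise the chain at sizes chosen to be informative while staying
lightweight: unit tests use 8 mm tubes on 1 mm isotropic grids; the
acceptance suite uses the full-scale geometry — a 15 mm × 50 mm cylinder on
a 0.5 mm grid (≈ 280 000 lumen voxels), a full PA tree on a 0.8 mm grid, a
1.2× scaled similarity replicate, 5 000 null replicates for type-I error
calibration at the study's 18/41 group sizes, 2 000 replicates for DeLong
p-value uniformity, a 100 000-replicate bootstrap oracle for the DeLong
variance, and cohorts of 2 000–5 000 patients for generator fidelity.

## Known limitations

Phantom realism as listed above; the nearest-centerline junction partition
is a geometric convention (real lumen boundaries at a bifurcation are
anatomically ambiguous — reported volumes near the junction depend on it at
the few-percent level); the cohort generator controls first and second
moments plus one pooled correlation per measurement, not the full joint
distribution; DICOM input is not supported (convert to NIfTI first); and the
published patient-level results (Table-3 AUCs, regression coefficients) are
not reproducible from synthetic data — the package reproduces exactly the
printed contingency statistics and validates everything else by
property-based oracles.
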