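# pamorph

Morphometry of the central pulmonary arteries from CT pulmonary angiography
(CTPA), for studies that relate artery geometry to pulmonary hypertension
(PH, mean pulmonary arterial pressure mPAP > 20 mmHg at right heart
catheterization).

The package implements the full measurement chain and its downstream
statistics:

- **Segmentation** — Hounsfield-window masking (−200…500 HU, inclusive),
  optional ROI cropping, and seeded region growing (connected-component
  selection at 6/18/26 connectivity).
- **Centerline** — topology-preserving 3D thinning (distance-ordered, six
  directional subfields, Bertrand–Malandain simple-point test), spur pruning,
  junction merging, penalized-spline smoothing with a normalized smoothing
  factor (default 0.5) and 1 mm control-point resampling, plus endpoint
  extension and sectionwise recentering.
- **Morphometry** — the nine quantities D/A/V for MPA, RPA and LPA:
  cross-sectional areas A(s) perpendicular to the centerline at every control
  point, vessel volume `V = Σ A(s_i)·Δs_i` over the trimmed extent (the plain
  sum of slice areas at 1 mm spacing), and the 1D diameter measured as the
  in-lumen chord on a 10 mm axial maximum-intensity-projection slab, 15 mm
  from the bifurcation. Sections near the bifurcation are partitioned
  between branches by a radius-normalized nearest-centerline rule.
- **Statistics** — Shapiro–Wilk-gated t/Wilcoxon group comparisons, Pearson
  χ² (no continuity correction) / Fisher exact tables, gated
  Pearson/Spearman correlation, ROC with Youden-optimal cutoffs and
  sensitivity/specificity/PPV/NPV/accuracy, DeLong comparison of paired
  AUCs, decision-curve analysis (net benefit `TP/N − (FP/N)·pt/(1−pt)`), and
  forward stepwise linear models predicting mPAP/SPAP/DPAP from the CT
  measurements.
- **Synthetic data** — CT-like tube phantoms (straight, arc, polyline;
  partial-volume rasterization; exact analytic truth) and a two-group
  synthetic cohort generator reproducing published group distributions and
  measurement–pressure correlations.

## Worked example

Generate a bifurcating pulmonary-artery phantom (trunk radius 18 mm, branch
radii 12 mm), run segmentation → centerline → measurement, and analyze a
synthetic 59-patient cohort:

```r
library(pamorph)

spec    <- make_pa_tree_spec(spacing = c(1, 1, 1))
phantom <- rasterize_phantom(spec)
mask    <- segment_vessel(phantom$volume, seed = c(0, 0, 30))
tree    <- extract_tree(skeletonize(mask), centerline_config(), seed = c(0, 0, 10))
measure_all(phantom$volume, mask, tree)
#> <vessel_measurements>
#>   MPA: D = 35.88 mm, A = 1016.00 mm^2, V = 49924.16 mm^3
#>   RPA: D = 23.38 mm, A = 446.05 mm^2, V = 19490.99 mm^3
#>   LPA: D = 23.38 mm, A = 446.67 mm^2, V = 19443.32 mm^3
```

The analytic truth for this phantom is D = 36/24/24 mm and
A = 1017.9/452.4/452.4 mm² — every value above is recovered within 3 %, and
the volumes match `π r² × trimmed extent` within 5 %.

```r
cohort <- attach_categoricals(generate_cohort(cohort_config()), seed = 20231213)
roc_table(cohort)[1:3, c("variable", "cutoff", "auc", "sensitivity", "specificity")]
#>   variable      cutoff       auc sensitivity specificity
#> 1    D_MPA    32.89626 0.8428184   0.7073171   1.0000000
#> 2    A_MPA   836.73249 0.9363144   0.8780488   0.8888889
#> 3    V_MPA 36125.55164 0.9227642   0.8780488   0.9444444

stepwise_pressures(cohort)$mPAP
#> predicted mPAP = -6.058 +0.0002006 * V_MPA +0.01175 * A_MPA +0.5834 * D_RPA  (R^2 = 0.722)

# published fixture equation applied to the measured phantom volume
predict_pressure(pa_pressure_models()$mPAP, measure_all(phantom$volume, mask, tree))
#> [1] 38.1325
```

A thin command-line wrapper with subcommands `phantom`, `cohort`, `segment`,
`centerline`, `measure`, `stats` and `run` (full pipeline from a YAML/JSON
config, with manifest and resume support) ships in `inst/cli/pamorph`.

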