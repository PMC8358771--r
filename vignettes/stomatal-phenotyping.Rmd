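---
title: "Bounding-box stomatal phenotyping: models, parameters and design notes"
author: "stomabox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounding-box stomatal phenotyping: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomabox)
```

## The measurement model

`stomabox` treats a stoma as an axis-aligned bounding box in a calibrated
micrograph. All geometry uses a corner-based, half-open convention
(`[xmin, xmax) × [ymin, ymax)`, origin top-left, x rightward, y downward, in
pixels), converted at the boundary from COCO's `[x, y, w, h]` layout. The
half-open corner convention was chosen because it makes area, intersection
and IoU arithmetic unambiguous; everything else follows from it.

Three phenotypes derive from the boxes of one microscopic field:

* **Stomatal density** `SD = N / A`, with `N` the number of detections and
  `A` the field area in mm². *All* detections count, including
  border-touching ones — a partially visible stoma is still a stoma in the
  field.
* **Stomatal size**: length = x-extent × μm/px, width = y-extent × μm/px.
  This assumes the acquisition protocol aligns the leaf's
  proximal–distal axis (and hence the guard-cell long axis) with the image
  x-axis; no rotation handling is attempted. Boxes touching a border are
  *excluded* from size statistics because the clipped extent underestimates
  the stoma. The border test uses a tolerance of ε = 0.5 px (configurable)
  since detector coordinates are real-valued while the underlying rule is
  stated on integer image limits. When every detection in a field is
  marginal, size means are reported as `NA` with `ss_defined = FALSE`
  rather than silently dropped.
* **File intervals**: grass stomata lie in horizontal files, so y-centres
  cluster tightly. Files are recovered by 1-D gap clustering: sorted
  y-centres start a new file where the gap exceeds `gap_factor` × median
  box height. The default `gap_factor = 1.5` sits between the within-file
  scatter (a few μm) and the smallest biologically seen file spacing
  (~130 μm ≈ 2.4 box heights), so the clustering is insensitive to the
  exact value; the method itself is our choice, as interval extraction
  procedures are rarely reported in enough detail to copy.

### Calibration

A `calibration()` object carries μm/px, the image dimensions, and the field
area. The ×4 default is 1.116 μm/px, 1024 × 768 px and 0.984 mm². The field
area is an *explicit constant*, not derived from the scale, because
published scale and area values are rounded independently and need not be
consistent at full precision (1024 × 768 × 1.116² = 0.979 mm², not 0.984);
`field_area_from_pixels()` provides the derived value when wanted.

## Detector evaluation

Matching is greedy in descending score order: each prediction takes the
still-unmatched ground-truth box of highest IoU, if that IoU reaches the
threshold. This is the standard detection-benchmark protocol and is
deterministic; it can in principle differ from the optimal assignment, so
the test suite checks it against brute-force enumeration on layouts whose
geometry (ground-truth boxes separated by more than a box size) guarantees
the optimum is attainable — the regime real imprints occupy, since stomata
do not overlap.

Average precision is the area under the score-ranked precision–recall
curve with **all-points interpolation** (the precision envelope). The
101-point COCO-style interpolation is available as an option
(`interpolation = "points101"`) because published mAP values do not always
state which convention their tooling used; on well-separated detections the
two differ by little. With a single category, mAP equals the pooled AP; the
category axis is retained only for format compatibility.

Non-maximum suppression is greedy by descending score with ties broken by
smaller area, then lower `xmin` — ties are vanishingly rare in practice, but
a defined order makes every pipeline stage bit-reproducible.

## The synthetic imprint generator

Real imprint datasets and trained detector weights are usually not
redistributable, so the generator provides scenes with exact ground truth
in the regimes reported for Triticeae leaf surfaces:

| parameter | default | meaning |
|---|---|---|
| `density_per_mm2` | 16.8 | abaxial bread-wheat regime; 23.2 for adaxial |
| `length_um_mean ± sd` | 87.2 ± 8 | hexaploid wheat stomatal length |
| `width_um_mean ± sd` | 54.4 ± 5 | hexaploid wheat stomatal width |
| `file_interval_um` | c(130, 230) | alternating abaxial file spacings |
| `file_interval_jitter_um` | 5 | placement jitter of each file |
| `stoma_y_jitter_um` | 3 | scatter of stomata about their file |
| `marginal_fraction` | 0.1 | stomata allowed to straddle a border |
| `sd_ss_coupling` | 0 | density–length coupling slope (μm per mm⁻²) |

The published species means (87.2 × 54.4 μm hexaploid down to
27.9 ± 3.5 × 17.3 ± 2.8 μm for *Brachypodium*) fix the size means and, for
the small-stomata regime, the standard deviations; the wheat per-stoma
standard deviations (8 and 5 μm) are our choice — large enough that
distributions of adjacent ploidy levels overlap, as published density plots
show, while keeping coefficients of variation below 10%. The per-image
stomata count is Poisson with mean density × area, thinned by rejection
sampling so no two boxes overlap (up to 100 × N placement attempts, then an
explicit capacity error): real stomata never overlap, and one-per-cell-file
placement makes overlap the right hard constraint. Placement failure is an
error, not a silent under-fill.

Rendering draws each stoma as a dumbbell — two filled ellipse lobes
flanking a darker pore rectangle, long axis horizontal — whose extremes
exactly fill the ground-truth box, so pixel-space and annotation-space
truth agree by construction. Optional Gaussian blur, additive noise and
dust specks roughen the image. This is deliberately *not* a photorealistic
imprint: no pavement cells, no subsidiary cells, no illumination field.
Consequently, passing tests establish the correctness of the measurement
and evaluation chain, not detector performance on real micrographs.

`generate_count_dataset()` draws per-image counts from a negative binomial
(`dispersion = Inf` giving the Poisson limit). Published sources rarely
report per-image count variance, so the Poisson default is our choice;
note that real stomatal counts tend to be *under*-dispersed relative to
Poisson (regular spacing along files), which the negative-binomial family
cannot represent. Power simulations run on these counts therefore give
conservative (larger) nonsignificance fractions than regular real data
would, while preserving every qualitative ordering (power rises with n,
falls with added measurement noise).

## Detector stand-ins

The `oracle_detect()` noise model (miss rate, coordinate jitter, Poisson
false positives) corrupts ground truth into realistic detection sets. True
boxes score uniform on `[score_threshold, 1]`; false positives on
`[score_threshold, 0.7]`, so score-ranked PR curves behave like a real
detector's (false positives concentrate at low scores). With all noise at
zero, the oracle returns ground truth verbatim — the property the
oracle-equivalence suite leans on.

`baseline_detect()` is a classical matched filter: normalized
cross-correlation against dumbbell templates over a small size grid, local
maxima above the score threshold, then NMS. Its default inference score
threshold is 0.5 — NCC is bounded by 1 and a half-correlation is a
reasonable floor; the value is configurable because no universal choice
exists. The baseline exists so the pipeline runs end to end without neural
weights; it is explicitly not equivalent to a trained neural detector and
no accuracy claims attach to it.

## Training-tile preparation

The preprocessing chain for detector training is resize ×0.5 (bilinear for
pixels, exact linear for coordinates), pad to 2048 × 1024 (width × height),
split into two 1024 × 1024 tiles. Two conventions had to be decided:

* **Padding side**: right and bottom only, keeping the origin fixed so box
  coordinates need no shift.
* **Seam-crossing boxes**: clipped into every tile they intersect, kept
  when the clipped fragment retains ≥ 50% of the original area
  (`min_box_retention`), otherwise dropped and reported in the `dropped`
  attribute. This keeps seam stomata while excluding slivers; published
  pipelines are typically silent on this point.

Tile ids are `parent_t<index>` in row-major order — stable and reversible.

## Statistics

`welch_t()` implements the unequal-variance t statistic with
Welch–Satterthwaite degrees of freedom and two-sided p-values, vectorised
internally so the 10,000-repetition power simulation is a single pass.
Degenerate inputs (both variances zero) take the convention p = 1 for
equal means, p = 0 otherwise. The implementation is checked against the
reference `stats::t.test` to 1 × 10⁻¹⁰ on randomized instances.

`power_simulation()` resamples a finite dataset *without replacement
within* a repetition (matching how one would subsample real images) and
independently across repetitions; generator functions are drawn fresh each
repetition. "Nonsignificant" is strictly `p > alpha`. One calibration note:
at n = 4 per group the Welch test is inherently conservative (empirical
size ≈ 0.044 at α = 0.05, a property shared by the reference
implementation), so the suite checks type-I calibration at n = 10, where
the nominal level is attained, and checks the n = 4 behaviour through
orderings rather than absolute size.

`pearson_test()` uses the t-based two-sided p-value on n − 2 df; |r| = 1 is
mapped to p = 0 directly rather than through an infinite statistic.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use 100–320 synthetic fields per
property, 1,000 randomized matching instances, and 10,000-repetition power
simulations — sizes at which the Monte-Carlo standard errors are far below
the tested tolerances while a full run stays comfortably interactive. Every
stochastic component takes an explicit integer seed; identical parameters
give bit-identical scenes, rendered images and simulation tallies.

## Interfaces

Batch work goes through the `run_*` functions (`run_simulate`,
`run_prepare`, `run_detect`, `run_evaluate`, `run_traits`, `run_stats`,
`run_demo`); `inst/cli/stomabox.R` wraps exactly these in a thin
`optparse`-based command-line entry point with a flat YAML configuration
(`pipeline_config()` / `read_pipeline_config()`), flags overriding file
values. The Labelbox-style reader parses a minimal documented dialect (one
record per image, `External ID`, top-level pixel dimensions, rectangle
objects with `top/left/height/width`) rather than tracking any particular
export schema version; records lacking dimensions error, non-rectangle
geometries are skipped with a warning.

## Known limitations

* Synthetic imagery is stylised; baseline-detector performance on it says
  nothing quantitative about real imprints.
* Stomata are assumed horizontally aligned; rotated or curved files are out
  of scope.
* Size measurement is box-based: no aperture, pore or guard-cell
  decomposition.
* The negative-binomial count family cannot express the under-dispersion
  of regularly spaced real stomata, so simulated power is a lower bound
  relative to equally sized real datasets.
* Greedy matching is only guaranteed optimal for non-overlapping layouts;
  dense overlapping detections (which NMS normally prevents) could differ
  from the optimal assignment.
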