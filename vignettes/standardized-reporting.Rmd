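---
title: "Standardized CNS tumor reporting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized CNS tumor reporting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurorads)
```

## Scope and data model

`neurorads` implements the computational pipeline behind standardized
pre- and postoperative reporting for CNS tumors: preprocessing of a 3D MR
volume, segmentation inference through a pluggable voxel classifier,
affine alignment to a reference atlas, feature extraction into a
hierarchical report, and a lesion-wise evaluation suite. The package
deliberately excludes the segmentation networks themselves (only the
patch-in/probability-out contract is defined), deformable registration
(an external backend can be plugged in as a point-mapping pair), and any
GUI.

Two containers carry all voxel data. A `volumetric_image` is a 3D scalar
array plus spacing (mm), origin (mm) and a 3×3 orthonormal direction
matrix; the physical position of voxel `(i, j, k)` is
`origin + orientation %*% (spacing * (idx - 1))`. A `label_mask` shares
that geometry and holds non-negative integers, constrained to {0, 1} for
tumor and brain masks. On import, NIfTI volumes carrying an orientation
are reoriented to the RAS anatomical convention, so that the first index
axis consistently runs left→right; without a fixed convention,
hemisphere and laterality logic would silently depend on acquisition
orientation. Masks may only be linked to an image when shape matches
exactly and spacing/origin/orientation agree within 1e-3 (mm); the rule
is deliberately strict because a mask resampled onto a subtly different
grid is a corrupted annotation, not a tolerable approximation.

## Preprocessing

The chain ahead of tumor inference is: isotropic resampling (default
0.75 mm), optional skull-stripping, upper-quantile intensity clipping
(default fraction 5e-4, i.e. the 0.05% highest values), then affine
normalization of the range to [0, 1].

Numerical choices worth recording:

* **Quantile definition.** "The 0.05% highest values" does not pin down
  an estimator; we use the linear-interpolation (type 7) quantile over
  the flattened volume. A configuration flag (`clip_within_brain`)
  restricts the statistic to brain-masked voxels instead; the default is
  the whole volume, which is well-defined even before a brain mask
  exists.
* **Resampling.** Output shape per axis is
  `round(shape · spacing / target)`, preserving physical extent to
  within one voxel. Sampling is cell-centered: output cell *j* reads
  input coordinate `0.5 + (j − 0.5) · out/in`, so both grids tile the
  same physical extent symmetrically and no half-voxel bias accumulates
  at the edges (with edge clamping outside the input lattice). The
  origin is shifted by half the spacing difference so physical positions
  remain exact. Label data must use nearest-neighbor interpolation —
  enforced, since linear interpolation invents label values.
* **Background.** After normalization to [0, 1], voxels outside the
  brain mask are set to 0, and patch padding uses the same constant; a
  constant volume normalizes to all-zeros rather than dividing by zero.
* **Degenerate inputs.** NaN/Inf voxels are rejected up front rather
  than propagated into quantiles.

## Inference modes

Tumor segmentation uses iterative **patch-wise** inference: a grid of
fixed-size patches (default 160³ voxels) is planned with the minimum
per-axis patch count that covers the volume at a requested minimum
overlap (default 0, i.e. abutting tiles), the final patch per axis
shifted back flush with the volume edge. Volumes smaller than the patch
are zero-padded. Overlapping predictions are fused by mean (default) or
max; mean was chosen as the default because it is the standard
test-time-averaging choice and is idempotent for any voxel-local
predictor. The central correctness property — tested exhaustively — is
that for a purely voxel-local predictor the stitched result is
voxel-identical to single-pass whole-volume application, under either
fusion rule and any overlap.

Brain segmentation uses **single-shot** inference over a downsampled
copy (working shape default 32³ in the orchestration layer), with the
probability map linearly upsampled back to the native grid before
thresholding. Binarization uses probability ≥ threshold with a default
of 0.5, configurable; no operating threshold is prescribed by the
segmentation models themselves.

## Atlas alignment and location profiling

Tumor features are computed in reference space: the patient image is
registered to the atlas template, the tumor mask is warped with
nearest-neighbor sampling through the inverse transform, and profiles
are computed against the atlas parcellations. Profiling in reference
space (rather than warping the atlas into patient space) keeps every
patient's features on one common grid.

The built-in registration is a deliberately simple **moment-matching
affine**: per-axis scales from ratios of intensity-weighted second
moments, translation from intensity-weighted centers of mass. For the
synthetic phantoms this recovers translations to numerical precision
and isotropic scales within a fraction of a percent; for real brains it
is only a coarse global alignment, and a deformable registration engine
should be plugged in through the `external` transform kind (forward and
inverse point maps). Registration of a constant image is refused as
degenerate rather than returning an arbitrary transform.

A location profile reports, per structure, the percentage of tumor
volume inside that structure, with an `unlabeled` bucket for tumor
voxels outside every labeled region; entries sum to 100 by construction
and serialized reports print them with two decimals. Laterality is the
left/right split of tumor volume over the hemisphere mask; the tumor is
flagged as midline-crossing when the minority side exceeds 5% of the
tumor volume (a configurable convention — the threshold keeps a
one-voxel spill across the midplane from being called "crossing"), and
exact 50/50 ties resolve to "left" so the output is deterministic.

## Reports

The preoperative report contains the tumor volume in both patient and
reference space (registration changes volume, so neither number is
redundant), laterality, the focus list, a multifocality flag, and one
profile per parcellation. Foci are connected components under
26-connectivity (default; 6 and 18 available) with a minimum reported
focus volume of 0.1 ml — satellite lesions below that are kept in the
total volume but not listed, since sub-0.1 ml components on typical
grids are a handful of voxels and dominated by segmentation noise. The
distance from the main focus to its nearest neighbor is reported as an
informational field only; no minimum inter-focus distance is imposed on
the multifocality call.

The postoperative report computes
`EOR = 100 · (V_pre − V_post) / V_pre` from volumes measured on each
mask's native grid, flags negative values as interval growth, and
assigns a residual-volume class with default bands: complete (residual
0), near-total (≤ 1 ml), subtotal (≤ 5 ml), partial (> 5 ml). Clinical
guideline cut-offs evolve, so the bands are pure configuration and are
validated for monotonicity; the defaults follow the residual-volume
style of current resection-grading proposals.

## Evaluation suite

Per patient: Dice (both-empty pairs scored 100, the convention a
tumor-free postoperative scan needs), a patient-level detection decision
(default any overlap; a minimum-Dice variant is available since the
appropriate strictness is cohort-dependent), and object-wise
recall/precision/F1 over connected components matched by any-overlap
(optionally a per-pair Dice threshold). Undefined ratios (zero
denominators) are reported as `NA`, never coerced to 0.

Cohorts are stratified by ground-truth volume at a configurable cut-off
(2 ml default; 5 ml suits lower-grade-glioma-style cohorts whose average
volumes are larger), with per-stratum counts and pooled metrics.
Cross-validation pooling uses the size-weighted mean and a pooled sd
built from the total sum of squares (within-fold variance plus
between-fold dispersion, n−1 denominator). This estimator was chosen
for a testable defining property: pooling *any* partition of a cohort —
including single-patient folds — reproduces the concatenated cohort's
mean and sd exactly.

## Synthetic data: what it does and does not show

The generators emulate just enough structure to exercise every
computation: an ellipsoidal bright "brain" (intensity 0.7) inside a
darker "head" (0.3) with optional Gaussian noise (sd 0.02 by default),
ellipsoid tumors of analytic volume 4/3·π·abc painted as intensity
offsets, a toy atlas (midline hemisphere split, cortical slabs,
a central subcortical core), and cohort trees with `T0`/`T1` timestamp
folders. Default cohort grids are 64³ at 1 mm; main-focus radii are
drawn so volumes straddle the 2 ml stratification cut-off, every second
patient carries a satellite focus, and the first patient has a complete
resection so the both-empty and EOR = 100% paths are always exercised.
The cohort manifest records analytic volumes and voxel-grid volumes
recomputed from the generating ellipsoid parameters — never read back
from the written files.

Passing tests on these phantoms establish that the *machinery* is
correct: geometry handling, stitching, feature arithmetic, report
assembly, metric definitions. They say nothing about segmentation
quality on real MR data, which depends entirely on the plugged-in
predictor; nor do ellipsoid lesions probe partial-volume effects,
infiltrative margins, or multi-sequence contrast. Realism of that kind
is explicitly out of scope.

Test and acceptance problem sizes (phantoms 32³–64³, cohorts of 3,
patch grids up to ~30 patches) were chosen as the smallest sizes at
which every geometric regime (multiple patches per axis, padding,
anisotropic spacing, bifocality, empty masks) still occurs; all checks
are properties or analytic comparisons, so nothing about them depends
on scale.

## Known limitations

* The built-in registration is affine and intensity-moment based; real
  deployments should supply a deformable backend.
* Laterality requires the atlas hemisphere mask to cover the tumor; a
  tumor wholly outside both hemisphere labels is an error rather than a
  silent 0/0.
* MetaImage/NRRD support is import-only (uncompressed MetaImage,
  attached raw/gzip NRRD); all outputs are NIfTI-1.
* Batch processing is sequential by design, mirroring the reporting
  workflow it reimplements; parallelism is future work.
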