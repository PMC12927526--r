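---
title: "Quantifying segmentation difficulty and scoring 3D instance predictions"
author: "vemtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying segmentation difficulty and scoring 3D instance predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vemtools)
```

## The problem

Mitochondria and other organelles imaged by volume electron microscopy
(FIB-SEM, SBF-SEM, serial-section SEM) form 3D instance-segmentation
targets with two characteristic failure modes. Where organelles pack
densely, boundary ambiguity produces *false merges*; where an organelle
narrows into thin necks, nanotunnels or branches, automated methods
produce *false splits*. Voxel-level scores hide both: a prediction can
label almost every foreground voxel correctly while fusing or
fragmenting the objects those voxels belong to. This package provides
(i) per-instance indices that quantify exposure to each failure mode,
(ii) an evaluation protocol that scores voxels and instances separately,
and (iii) the standardization and I/O operators needed to apply both to
volumes in a common on-disk layout.

## Difficulty indices

All morphology operates on the voxel grid with a cubic box structuring
element of radius $r$ (the $(2r+1)^3$ neighborhood; $r = 1$, the
$3\times3\times3$ box with full 26-connectivity, is the default
everywhere). For instance mask $M_i$:

* $\mathrm{DCI}_i = \#\{j \neq i : \mathrm{Dilate}(M_i, B_{r_d}) \cap M_j \neq \emptyset\}$.
  At $r_d = 1$ this counts the distinct instances whose masks lie within
  Chebyshev distance 1 of $M_i$ — the neighbors a one-voxel boundary
  error could fuse with. Each neighbor is counted once regardless of
  contact area. The dilation radius models expected boundary
  uncertainty: larger $r_d$ asks about coarser boundary errors, and DCI
  is non-decreasing in it.

* $\mathrm{EFI}_i = \max(0,\, N_{\mathrm{comp}}(\mathrm{Erode}(M_i, B_{r_e})) - 1)$.
  A compact object survives a mild erosion in one piece (EFI 0); an
  object held together by structures thinner than $2r_e + 1$ voxels
  falls apart, and EFI counts the extra fragments.

Three choices here were genuinely open and are fixed as follows:

* **Fragment connectivity.** Components of the eroded mask are counted
  under 26-connectivity, matching the full-box structuring element; the
  `connectivity` argument exposes 6 and 18 for sensitivity analyses.
* **The clamp.** One might assume an eroded object always retains a
  component, but any instance everywhere thinner than $2r_e+1$ voxels
  (a one-voxel sheet or filament) erodes to nothing, which would give
  $\mathrm{EFI} = -1$. A vanished object creates no fragments, so EFI is
  clamped at 0.
* **Border handling.** Outside-volume voxels count as background in both
  directions: dilation clips at the bounds and voxels within $r$ of the
  border erode away. Instances touching the border are *not* excluded;
  their EFI simply reflects that the border cuts them.

Morphology is defined in voxel units even for anisotropic data
(8×8×30 nm serial-section volumes): the box kernel is a statement about
label-map geometry, not physical distance. Physical spacing is carried
on every volume and used for reporting and resampling only.

Per-instance computation is restricted to the instance's bounding box
(padded by $r_d$ for dilation). This is exact — the dilated mask cannot
leave the padded box, and the mask is background beyond it — and it is
what makes per-instance loops tractable on benchmark-scale volumes. The
test suite asserts exact agreement with whole-volume coordinate-set and
flood-fill oracles on randomized volumes.

## Evaluation protocol

`semantic_accuracy()` binarizes both volumes (any positive label is
foreground) and reports $TP/(TP+FP+FN)$ over voxels — the foreground
Jaccard index, insensitive to how the foreground is partitioned.

`evaluate()` adds the instance tier: the dense IoU matrix between
ground-truth and predicted instances (computed in one sparse pass over
co-foreground voxels), an optimal one-to-one assignment maximizing total
IoU (Hungarian algorithm, via `clue::solve_LSAP` on the zero-padded
square matrix), then a threshold: assigned pairs with IoU ≥ τ are TP,
everything else is unmatched. Unmatched predictions are FP, unmatched
ground truth FN, and instance accuracy is again $TP/(TP+FP+FN)$.

Decisions worth recording:

* **Assign first, threshold after** (default). Zeroing sub-τ entries
  before solving is available as `premask = TRUE` for comparison with
  toolkits that formulate it that way; with distinct IoU values the TP
  set is the same.
* **Boundary semantics.** IoU exactly equal to τ counts as matched. This
  matters in practice: a prediction that merges two equal-size objects
  has IoU exactly 0.5 with each, so at τ = 0.5 one of them is still a
  TP.
* **Ties.** Rows and columns are sorted by instance id before solving,
  so equal-cost optima resolve deterministically; TP/FP/FN counts are
  identical across optima unless IoU values tie exactly at the
  threshold.
* **Degenerate inputs.** Both sides empty scores 1.0 at both tiers
  (nothing to find, nothing found); one side empty scores 0.0.
* **Size strata.** `size_bins` stratifies the instance counts by voxel
  count. Matched pairs and false negatives are binned by the
  *ground-truth* instance's size (ground truth defines the reference
  population); an unmatched prediction has no ground-truth partner and
  is binned by its own size. No standard bin edges exist for organelle
  volumes; 500 voxels (the annotation floor) and factors of ten above
  it are a reasonable default, and the edges are fully configurable.
* **Multi-volume aggregation.** `aggregate_evaluations()` pools TP/FP/FN
  across volumes before the ratio by default — the convention that
  weights every instance equally; `mode = "mean"` averages per-volume
  accuracies instead, which weights volumes equally. Published
  benchmarks do not always say which they used, so both are first-class
  and the result records the mode.

`sweep_tau()` reuses one IoU table across thresholds; instance accuracy
is non-increasing in τ because raising the bar can only demote matches.

## Standardization

* `reindex_instances()` relabels to consecutive 1..N by first voxel in
  (z, y, x)-lexicographic scan order — a deterministic rule so ids are
  reproducible across runs and platforms.
* `filter_min_volume()` removes instances below a voxel-count floor
  (default 500, the annotation inclusion threshold). The boundary is
  inclusive: exactly 500 voxels survives. The log records the voxel
  spacing at which the filter ran, since a volume threshold is only
  meaningful at a stated resolution; difficulty reports are conventionally
  computed after filtering, and the report carries its parameters.
* `resample_image()` implements the 16 nm standardization pathway:
  separable trilinear interpolation at voxel centers, preceded on each
  downsampled axis by a Gaussian anti-aliasing prefilter. No particular
  filter is canonical; a Gaussian with $\sigma = (f-1)/2$ voxels for
  downsampling factor $f$ (truncated at $3\sigma$, edge-replicated) is
  standard practice and is what the spectral test verifies. Anisotropic
  volumes are simply left at native spacing by not calling the
  resampler; nothing in the package forces isotropy.
* `resample_labels()` uses nearest-neighbor sampling so no
  interpolation-created labels can appear; a majority-vote block mode is
  offered for integer factors, where background competes on equal terms
  with instance labels.
* `check_topology()` reports instances whose voxels form more than one
  connected component — annotation errors, or legitimate border
  crossings that deserve review.

## The phantom generator

`generate_phantom()` builds the study conditions the metrics are
validated under. Primitives are rasterized from analytic inequalities
(Euclidean balls, capsule tubes, cube-and-bar dumbbells, three-armed
orthogonal trees) and placed by rejection sampling under a pairwise
Chebyshev-gap constraint, with the exclusion zone computed in a padded
frame so the gap holds across bounding boxes. Defaults — a 48³ grid at
16 nm isotropic spacing, 8 instances, primitive size parameter 3–5
voxels, gap 1 — give instance sizes of a few hundred to a few thousand
voxels, the scale of real mitochondria at standardized resolution, while
keeping any single test volume under a megavoxel. Two constructions
carry guarantees used throughout the tests: `abutting_pairs` places
face-sharing cube pairs (every instance has DCI ≥ 1 at radius 1), and
dumbbells with `neck_radius = 1` have a one-voxel bar that a radius-1
erosion removes (EFI ≥ 1).

`perturb_prediction()` degrades a ground truth with logged events whose
instance-level consequences are computable from the log alone when the
events are geometrically independent: a kept instance is a TP; a drop an
FN; a spurious blob (placed at Chebyshev distance ≥ 2 from all
foreground) an FP; a merge of sizes $(s_1, s_2)$ gives one TP and one FN
iff $\max(s_1,s_2)/(s_1+s_2) \ge \tau$, else two FN and one FP; a split
with fragments $(p_1, p_2)$ gives one TP and one FP iff
$\max(p_1,p_2)/(p_1+p_2) \ge \tau$, else one FN and two FP.
`predict_counts()` implements this bookkeeping and refuses logs with
boundary-noise events, whose IoU effects are not log-predictable.

What the phantoms do *not* emulate: EM texture and noise (the intensity
channel is a smoothed indicator plus Gaussian noise, sufficient only for
I/O tests), realistic organelle shape statistics, partial-volume and
section artifacts, or annotation noise in the ground truth itself.
Passing tests therefore demonstrate that the *metrics and protocol* are
computed correctly and behave as designed — not that any particular
segmentation model performs well on real tissue.

## Numerical and scale choices

Random-volume verification runs at sizes where brute force is exact and
fast: 100 volumes of 12–24 voxels per side with up to 10 instances for
the morphology/difficulty oracles, 500 random IoU tables up to 6×6
against factorial enumeration for the matcher, and 50 seeded
phantom/perturbation rounds for the log-recovery check; the whole suite
runs in well under a minute. Assignment comparisons use a 1e-12
tolerance on total IoU (sums of doubles); NIfTI round-trips are asserted
bit-exact for uint16 labels and to float32 precision (1e-6 relative) for
images. Checksums default to SHA-256; the manifest format is the
`sha256sum` line format, and the algorithm is an argument, not a
constant.

## Limitations

* DCI/EFI are voxel-grid descriptors: at 8×8×30 nm, a one-voxel
  erosion removes 30 nm along z but 8 nm in-plane. The optional
  anisotropy-aware reading is to run the indices at a resampled
  isotropic resolution and say so; the indices themselves stay
  voxel-defined.
* The Hungarian tier scores detection-style errors; it does not grade
  boundary quality beyond IoU, and deliberately excludes panoptic
  quality, Adapted Rand and variation-of-information, which weight
  errors differently.
* `label_components()` builds a voxel-adjacency graph; on volumes far
  larger than benchmark test blocks, memory for the edge list becomes
  the binding constraint before time does.
* The dataset-descriptor reader validates the documented filename
  conventions and split disjointness; it deliberately passes unknown
  `dataset.json` keys through untouched rather than enforcing a schema
  the ecosystem has not fixed.
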