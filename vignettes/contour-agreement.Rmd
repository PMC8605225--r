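---
title: "Quantifying interrater contour agreement: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interrater contour agreement: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concord)
```

## The problem

When several radiation oncologists independently delineate the same
structure on the same MRI — here the prostate, the paired neurovascular
bundles (NVB) and the paired internal pudendal arteries (IPA), the
structures that matter for erectile-function-sparing prostate radiotherapy
— their contours disagree. Before such structures can be spared in
MR-guided radiotherapy, that interobserver variability has to be
quantified. `concord` implements the standard quantification: every
unordered pair of raters is compared per patient and per structure with
three complementary metrics, and the cohort is summarized as median with
interquartile range.

Because elongated vessel-like structures continue cranially far beyond the
clinically relevant region, raters also disagree on how far superiorly to
contour at all. Comparing raw contours would punish that longitudinal
disagreement twice. The pipeline therefore first *harmonizes* contours:
per patient and structure, all raters' masks are cropped to the maximal
superior–inferior interval common to all of them, and a subset consisting
of the exact inferior half of the harmonized NVB is derived, since the
inferior NVB (midgland to apex) lies closest to the prostate and is where
sparing conflicts with target coverage.

## Data model

Masks live on a `grid_spec`: a regular voxel lattice with integer
dimensions, positive anisotropic spacing in mm, a physical origin, and a
designated superior axis (default: the third axis, increasing toward the
head, the usual axial-stack convention). Indices are 0-based in the
documentation and coordinates always refer to voxel *centers*:
`coordinate = origin + index * spacing`. A `structure_mask` is a binary
occupancy array on such a grid plus patient/rater/structure metadata. Any
non-zero voxel in a loaded file counts as occupied.

I/O goes through NIfTI (read/write, via RNifti) and NRRD (read-only).
Clinical contours drawn as closed planar polygons per axial slice can be
rasterized with the even–odd rule: a voxel is occupied iff its center lies
inside an odd number of that slice's polygons, so nested polygons cut
holes. Points exactly on an edge are resolved by a fixed half-open
convention (crossings count for edges spanning the test ordinate half-open
in y, and only strictly to the right in x), which makes counts
deterministic and lets abutting polygons tile without double coverage.

## The three metrics

For masks $A$, $B$ on a shared grid with voxel volume $v$:

* **Dice similarity coefficient**, $\mathrm{DSC} = 2|A\cap B|/(|A|+|B|)$ by
  voxel counts; 0 = no overlap, 1 = identical. Volumes are reported in cc
  as $|A| \cdot v / 1000$.
* **Average surface distance** (symmetric, 3D, in mm). The surface of a
  mask is the set of occupied voxels with at least one of their 6
  face-neighbors unoccupied (grid border counts as unoccupied), taken as
  voxel-center points. With $d(p, S)$ the Euclidean distance from point
  $p$ to the nearest point of surface $S$, the metric is the mean of the
  pooled multiset $\{d(p, S_B)\}_{p \in S_A} \cup \{d(q, S_A)\}_{q \in
  S_B}$.
* **Hausdorff distance** (maximum surface distance):
  $\max(\max_p d(p,S_B), \max_q d(q,S_A))$ — the worst-case boundary
  discrepancy. By construction it bounds the average surface distance from
  above.

Three choices here were genuinely open and are worth stating:

* *Surface model.* Surfaces are boundary-voxel centers under
  6-connectivity, and distances are point-to-point Euclidean distances in
  physical mm. Mesh-based (marching-cubes) surfaces would differ by a
  sub-voxel offset; the voxel-center convention is the dominant published
  one and — decisively for testing — is checkable against a brute-force
  all-pairs oracle to $10^{-9}$ mm, which the test suite does on seeded
  random masks.
* *Symmetrization.* "Symmetric" average surface distance is ambiguous
  between pooling both directed distance multisets (weighting each surface
  by its point count) and averaging the two directed means with equal
  weight. The pooled form is the default; `mode = "mean_of_means"` selects
  the alternative. The pooled mean is computed from the two directed sums,
  not a concatenated vector, so the result is bit-identical under argument
  swap.
* *Percentile.* The Hausdorff distance is the exact maximum by default; a
  percentile variant (e.g. 95) exists behind `hausdorff_percentile` but is
  off, since the study design this reproduces used the maximum.

The fast path is an exact Euclidean distance transform
(Felzenszwalb–Huttenlocher, generalized to anisotropic spacing, in C++):
the distance map of one mask's surface voxels is sampled at the other
mask's surface voxels. Per (patient, structure) the per-rater surface maps
are computed once and shared across all rater pairs.

## Harmonization conventions

* The common interval is the intersection of all raters' extents (lowest
  to highest occupied slice by center coordinate; internal empty slices do
  not shrink an extent). An empty intersection is an error naming the
  patient and structure, never a silent skip.
* The reported "distance between superior and inferior border" counts
  whole slices: `n_slices × slice_spacing`, i.e. outer border to outer
  border, one slice spacing more than the center-to-center span.
* The *exact inferior half* keeps slices whose centers lie at or below the
  physical midpoint of the harmonized interval. With an even slice count
  this is exactly the lower half; with an odd count the middle slice is
  included, erring toward the apex-side region where agreement matters
  clinically.
* The prostate is never cropped and gets no inferior-half subset; its
  border-distance cell renders `NA`.
* Harmonization is per structure, per patient — never across patients, and
  no in-plane trimming of any kind.

Volumes of cropped structures are reported post-harmonization by default
(`volume_stage = "pre_harmonization"` switches to as-contoured volumes),
so the volume row describes the same contours the agreement metrics were
computed on.

Summaries use the median and quartiles by linear interpolation between
order statistics (`stats::quantile` type 7, the default of mainstream
statistics software); the rule is pinned so reported numbers are exactly
reproducible. Report tables are rounded to 2 decimals in both the CSV/JSON
and human-readable renderings, which agree by construction. No hypothesis
tests are performed anywhere — the pipeline is purely descriptive.

## The synthetic cohort

No clinical masks accompany the package, so a seeded phantom generator
provides a fully self-contained test bed with known ground truth.

The phantom places, on a 96 × 96 × 40 grid at 1 × 1 × 2 mm (2 mm slices;
pelvic MR protocols for this task use slice spacing of this order, and it
makes harmonized border distances whole even numbers of mm):

* the **prostate** as an ellipsoid (default semi-axes 22 × 18.5 × 20 mm,
  ≈ 34 cc);
* each **NVB** as a tube hugging the prostate's dorsolateral surface,
  whose radius widens toward the superior end (4.2 → 5.8 mm), mirroring
  the real NVB becoming more divergent and diffuse toward the base; its
  slice range extends 3 slices beyond the prostate at both ends
  (seminal-vesicle base to urogenital diaphragm, ≈ 48 mm, ≈ 4 cc);
* each **IPA** as a lateral tube (radius 4 mm, ≈ 2.2 cc) whose centerline
  turns from posterior to ventral going superior, the artery's
  characteristic course into the pelvis.

Structures are pairwise disjoint and fit the grid with a 2-voxel margin by
construction (violations are errors, not warnings). Per-patient anatomical
variation jitters the free parameters by at most ±10%, a magnitude chosen
as plausible population variation rather than fitted to anything.

A simulated rater perturbs ground truth through a `rater_noise_model`:

1. **Extent jitter** moves each cranio-caudal end by a uniform draw from
   `-j..+j` whole slices; added slices copy the nearest true end slice.
2. The jittered truth becomes a signed Euclidean distance field (negative
   inside), and the rater's mask is `sdist ≤ margin_bias + field`, where
   `field` is a smooth random displacement (sum of 10 low-frequency cosine
   harmonics, rescaled to SD `surface_sigma_mm`). Low-order harmonics keep
   simulated contours simply connected, like human contours; i.i.d. voxel
   flips would not.
3. With `divergence_gain` $g > 0$ the field's amplitude scales linearly
   from 1 at the inferior end to $1+g$ at the superior end — the simulator
   analogue of the superior NVB being harder to distinguish.

Thresholding the exact distance field makes a pure margin bias an exact
physical-distance dilation: `+1` mm at 1 mm spacing is exactly the 1-voxel
face dilation, which the tests verify against a morphological oracle. One
asymmetry of the voxel-center convention is documented rather than hidden:
erosion removes voxels strictly *closer* than `|b|` to the background, so
an erosion of exactly one voxel spacing is a no-op while the matching
dilation is not.

All randomness is local: `simulate_rater` seeds a temporary RNG from the
model's seed and restores the global state, and `generate_cohort` derives
one seed per (patient, rater, structure) from its single master seed, so
identical master seeds give voxel-identical cohorts and no two masks share
a noise realization.

Default noise (σ = 1.5 mm, per-rater margin biases 0/+0.5/−0.5/+1.0 mm,
extent jitter 2 slices, divergence gain 1.0) is *illustrative*: it is
chosen to produce the degree of disagreement typical for small tubular
pelvic structures (median pairwise DSC roughly 0.4–0.8, large-structure
DSC markedly higher), not calibrated to any clinical cohort — no per-rater
bias estimates exist to calibrate against.

## What the synthetic tests do and do not show

The simulator reproduces the *mechanisms* of disagreement (smooth boundary
displacement, systematic margins, longitudinal truncation, superior
divergence) but none of the *causes* (image contrast, sequence quality,
training, anatomical ambiguity). Passing tests therefore demonstrate that
the pipeline measures what it claims to measure — exact metric values
against oracles, exact design counts, correct harmonization arithmetic,
and the qualitative signature that superiorly-weighted noise makes
inferior-half agreement best — not that any particular clinical cohort
would show specific DSC values. Real cohorts differ in rater correlation
structure, in-plane anisotropy of errors, and anatomy-dependent
difficulty, none of which the low-order harmonic field models.

## Numerical and degenerate-input conventions

* Grid equality tolerance: 10⁻⁴ mm on spacing and origin; dimensions
  exact.
* Dice of two empty masks is undefined and raised as an error; surface
  distances require both masks non-empty.
* A mask emptied by cropping, a rater noise model that erases a structure,
  and a missing spacing field in an input file are all distinct, typed
  errors.
* Pipeline failures (missing mask, no longitudinal overlap) are logged per
  (patient, structure) and skipped; a configurable threshold aborts the
  run when exceeded. Record counts plus logged failures always add up to
  `C(n_raters, 2) × n_patients` per structure.
* Pipeline runs consume no randomness at all; reports are byte-identical
  across reruns and invariant to manifest row order.

## Problem sizes used in the shipped checks

The test suite exercises the full main-study geometry once — a 15-patient
× 4-rater cohort on the default grid (105 harmonized structure sets, 630
pair records) — and otherwise uses 5-patient cohorts, 12³ grids for the
brute-force oracle comparisons (100 seeded pairs), and 50³ grids for the
parameter-recovery checks. These sizes were chosen so the whole suite runs
comfortably on a laptop while still covering every code path at the real
cohort's scale.
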