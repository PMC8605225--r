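# concord

Interrater agreement analysis of 3D structure delineations (contours) for
radiotherapy contour quality assurance.

When several radiation oncologists independently contour the same
structure — here the prostate and the paired neurovascular bundles (NVB)
and internal pudendal arteries (IPA) that matter for erectile-function
sparing in MR-guided prostate radiotherapy — their contours disagree, and
that disagreement must be quantified before such structures can be spared
clinically. `concord` implements the standard pairwise quantification:

* **Dice similarity coefficient** — DSC = 2|A∩B| / (|A|+|B|) by voxel
  counts (0 = no overlap, 1 = identical);
* **symmetric 3D average surface distance** (mm) — mean nearest-neighbor
  Euclidean distance between the two masks' boundary-voxel surfaces,
  pooled over both directions;
* **Hausdorff distance** (mm) — the maximum of the two directed maximal
  nearest-surface distances, i.e. the worst-case boundary discrepancy;

computed for every unordered rater pair (4 raters → 6 pairs per patient),
after *harmonizing* each structure's contours to the maximal
superior–inferior extent common to all raters and deriving the exact
inferior half of the NVB (≈ prostate midgland to apex, where sparing
conflicts most with target coverage). Results are summarized per structure
as median (IQR) in a report table, alongside per-rater volumes (cc) and
per-patient harmonized border distances (mm).

Because clinical delineations are rarely shareable, the package includes a
seeded synthetic phantom-cohort generator: ellipsoid-plus-tubes pelvic
anatomies with per-patient variation, and a parameterized rater-noise
model (smooth surface displacement, systematic margin bias, cranio-caudal
extent jitter, superior-weighted divergence noise) so the entire pipeline
can be exercised against known ground truth.

## Worked example

```r
library(concord)

dir <- file.path(tempdir(), "demo")
man <- generate_cohort(n_patients = 5, n_raters = 4, master_seed = 42,
                       out_dir = dir)          # 100 NIfTI masks + manifest
study <- run_agreement_study(man)              # harmonize + all pair metrics
build_report(study)
```

```
                                                           NVB_left
Overall volume (cc)                                        5.11 (3.89 - 5.46) [n=20]
Overall distance between superior and inferior border (mm) 48.00 (48.00 - 48.00) [n=5]
Overall Dice similarity coefficient                        0.63 (0.56 - 0.67) [n=30]
Overall average surface distance (mm)                      1.73 (1.35 - 2.06) [n=30]
Overall Hausdorff distance (mm)                            6.85 (5.74 - 7.86) [n=30]
                                                           NVB_left_inf_half
Overall volume (cc)                                        1.83 (1.51 - 2.77) [n=20]
Overall distance between superior and inferior border (mm) 24.00 (24.00 - 24.00) [n=5]
Overall Dice similarity coefficient                        0.66 (0.55 - 0.71) [n=30]
Overall average surface distance (mm)                      1.32 (1.00 - 1.66) [n=30]
Overall Hausdorff distance (mm)                            4.58 (3.81 - 5.65) [n=30]
```

(two of seven structure columns shown). Reading the left NVB column: four
simulated raters contoured it in 5 patients; after cropping to the common
extent the contours span 48 mm cranio-caudally and hold ≈ 5 cc; the median
of the 30 rater-pair comparisons (6 pairs × 5 patients) overlaps at DSC
0.63 with boundaries typically 1.7 mm apart and a worst-case boundary
discrepancy of 6.9 mm. The inferior half agrees better (DSC 0.66, average
surface distance 1.32 mm) — the expected signature of noise that grows
toward the superior end, where the real NVB is diffuse and hard to
delineate.

`write_study_outputs(study, "report")` writes `pair_metrics.csv` (one row
per patient × structure × rater pair), `summary_table.csv` /
`summary_table.json`, and `config_used.json`; reruns are byte-identical.

Individual building blocks are exported too: `read_mask()` /
`write_mask()` (NIfTI, plus read-only NRRD), `rasterize_slice_polygons()`
for per-slice polygon contours, `dice()`, `avg_surface_distance()`,
`hausdorff()`, `harmonize()`, `inferior_half_set()`, `simulate_rater()`.
A command-line wrapper lives at `inst/cli/concord`
(`concord synth ... | concord run ...`).

## Documentation

The methods vignette (`vignettes/contour-agreement.Rmd`) documents the
surface model and symmetrization conventions, the harmonization and
inferior-half rules, the phantom geometry and the rater-noise model, the
numerical conventions, and what the synthetic tests do and do not
demonstrate about clinical data.
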