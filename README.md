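# ipvv — diameter-resolved intrapulmonary vessel volume quantification

`ipvv` is an R toolkit for quantitative morphometry of segmented pulmonary
vessels from CT pulmonary angiography (CTPA). Given a 3D vessel mask
(binary, or labeled 1 = artery / 2 = vein) with known voxel spacing, it
reconstructs a spatially continuous per-voxel **radius field** and turns it
into the vessel-volume metrics used to study pulmonary vascular pruning:

* **TIPVV / IPVVa / IPVVv** — total / arterial / venous intrapulmonary
  vessel volume, in mL and BSA-normalized mL·m⁻²;
* volumes within five diameter bins — (0.8, 1.6], (1.6, 2.4], (2.4, 3.2],
  (3.2, 4.0] and > 4.0 mm (strict lower, inclusive upper boundaries), with
  the sub-0.8 mm remainder reported separately;
* diameter- and compartment-color-coded label volumes for 3D rendering;
* two-group comparison tables (normality-gated t-test / Mann–Whitney U)
  and robust-SE regression for group effects adjusted by age, sex and BSA.

It is aimed at imaging researchers who already have segmentation masks
(the segmentation model itself is out of scope) and want reproducible,
validated downstream quantification.

## The radius algorithm

For each compartment independently:

1. **Centerline & distance map** — topology-preserving 3D thinning
   extracts a one-voxel-wide skeleton; an exact anisotropic Euclidean
   distance transform (EDT) gives each foreground voxel its distance in mm
   to the nearest background.
2. **Radius assignment** — at a centerline voxel the boundary distance is
   the cross-sectional radius: `r(c) = EDT(c)` exactly.
3. **Hierarchical radius propagation** — every non-centerline vessel voxel
   `v` considers candidate centerline points `c` with
   `dist(v, c) < r(c)` (it must lie inside the candidate's inscribed
   sphere) and takes the radius of the geometrically closest candidate;
   voxels with no candidate fall back to the globally nearest centerline
   point and are flagged in a provenance map. Ties prefer the larger
   radius, then the smaller voxel index, so the result is deterministic —
   and the accelerated search is bit-identical to a brute-force scan by
   construction (and by test).

Body surface area uses DuBois:
`BSA(m²) = Weight(kg)^0.425 × Height(cm)^0.725 × 0.007184`.

A synthetic phantom module (cylinders, bent tubes, random bifurcating
trees with analytic ground-truth radii) and a two-group cohort simulator
make the whole pipeline testable without patient data.

## Worked example

```r
library(ipvv)

# a bifurcating phantom with root radius 2.6 mm (seed-reproducible)
ph <- make_tree(root_radius_mm = 2.6, depth = 2L, scale = 0.7, seed = 5L)
ph$mask
#> <voxel_mask> 24 x 28 x 55, spacing (1, 1, 1) mm
#>   foreground: 1027 voxels (artery 1027, vein 0)

rf <- vessel_radius_field(ph$mask)
rf
#> <radius_field> 1027 voxels (all), radius 1.00-2.24 mm, fallback 14.2%

subj <- compute_bsa(as_subject_table(data.frame(
  id = "s1", group = "control", age = 45, sex = "male",
  height_cm = 164, weight_kg = 66)))
round(subj$bsa, 2)
#> [1] 1.72

rep <- normalize_report(bin_volumes(rf, ph$mask), subj)
rep$totals
#> TIPVV IPVVa IPVVv
#> 1.027 1.027 0.000
```

The radius range 1.00–2.24 mm reflects the tree's taper (2.6 → 1.82 →
1.27 mm by the 0.7 scaling) as seen through the voxel grid; `fallback
14.2%` is the fraction of voxels — concentrated at the two bifurcations —
whose radius came from the unconstrained nearest centerline point rather
than an inscribed-sphere candidate. In the binned report every voxel
contributes 1 mm³ = 0.001 mL to the bin holding its diameter; here the
1027 foreground voxels split 65 / 193 / 311 / 458 across the 1.6–2.4,
2.4–3.2, 3.2–4.0 and > 4 mm bins (columns `volume_ml` and
`volume_ml_per_m2` carry the same split in mL and mL·m⁻²).

Cohort-level statistics on simulated data:

```r
ct <- make_cohort(50, effect = c("IPVVa_0.8-1.6mm" = 0.7), seed = 1L)
compare_groups(ct, "IPVVa_0.8-1.6mm")
#> IPVVa_0.8-1.6mm: 4.88 (3.84, 6.00) vs 3.52 (2.78, 4.76) |
#>   mann_whitney_u Z = 4.047, p = 5.195e-05 *
compare_groups(ct, "TIPVV")
#> TIPVV: 105.85 ± 12.44 vs 104.88 ± 11.54 | student_t t = 0.404, p = 0.6872
```

The planted 30% reduction in the smallest arterial bin is detected
(median 4.88 vs 3.52 mL·m⁻², p < 0.001) while the untouched total stays
null. `compare_all()` produces the full 13-row table (3 totals + 5
arterial + 5 venous bins) and `render_report()` writes it as CSV, text
and optional boxplots; `adjusted_regression()` adds the robust-SE group
effect on IPVVa.

## Command line

`inst/cli/ipvv.R` wraps the same functions:

```sh
Rscript inst/cli/ipvv.R phantom  --kind tree --radius 2.6 --depth 2 \
    --seed 5 --out-mask mask.nii.gz --out-truth truth.nii.gz
Rscript inst/cli/ipvv.R quantify --mask mask.nii.gz --subjects subj.csv \
    --id s1 --out report.json --color-out colors.nii.gz
Rscript inst/cli/ipvv.R report   --cohort cohort.csv --out results --plots
```

Masks are read/written as NIfTI-1 (`.nii`, `.nii.gz`) or NRRD (`.nrrd`);
subject tables as CSV with header `id,group,age,sex,height_cm,weight_kg`.

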