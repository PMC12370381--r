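# srsdvh

Quality-assurance tooling for dose-volume-histogram (DVH) accuracy in
intracranial stereotactic radiosurgery (SRS). The package answers a
commissioning question every SRS physicist faces: *how much do the CT slice
thickness (ST) and the dose-calculation grid (DG) distort structure
volumes, isodose volumes and plan-quality indices for millimetre-scale
targets with steep dose gradients?*

It provides:

* **Analytical ground-truth phantoms** — bundles of spheres (3-20 mm
  diameter, randomly placed within a voxel) contoured on a
  0.6 × 0.6 × 1 mm CT lattice, each with a closed-form radial dose model
  (100% of prescription at the target surface, halving every *g* = 3 mm
  beyond it, capped at 125% inside), so structure volume and every isodose
  volume have exact reference values (πD³/6 and (4/3)πr_L³ with
  r_L = R + g·log₂(100/L)).
* **A contour-based geometry engine** — supersampled point-in-polygon
  rasterisation (even-odd rule, boundary inclusive, slab z-assignment) with
  parabolic end-capping for volume reporting, plus a Monte Carlo volume
  oracle.
* **A DVH engine** — mini-voxel isodose volumes and cumulative DVHs with
  tricubic (validation) or trilinear (TPS-emulating) dose interpolation;
  D95, V30Gy, Paddick conformity index CI = TV_PIV²/(TV·PIV) and gradient
  index GI = V50%/V100%.
* **Clinical-like multi-lesion cases** — seeded irregular lesions in the
  6-30 mm diameter groups with 1.5-cm evaluation shells and a low-dose
  bath.
* **The discretisation study** — V_dose ratios against reference volume
  with Spearman rank analysis and a power-law fit y = a·x^b + c (NRMSE
  relative to the range), Wilcoxon signed-rank comparisons per diameter
  group (exact null distribution up to 25 pairs, ties included), paired
  effect sizes and required sample sizes.

## Worked example

Generate fifty 3-mm spheres with randomised sub-voxel centres and compare
the computed volumes and isodose volumes with their closed forms:

```r
library(srsdvh)
bundle <- make_ground_truth_bundle(diameters = 3, n_per_diameter = 50, seed = 7)
val <- validate_bundle(bundle)
format_validation_table(val)
```

```
  Target diameter (mm)       Target Volume              V100%               V50%
1                    3 -0.32 (-3.55, 2.21) 0.84 (-2.80, 3.75) 0.04 (-0.21, 0.24)
```

Each cell is the signed mean (and range) of the local percentage difference
`100·(computed/analytic − 1)` over the 50 spheres: volumes of these
~14 mm³ targets are recovered to about 1% on average (3.5% worst case),
V100% on a 1-mm dose grid to under 4%, and V50% to a fraction of a percent
— the accuracy a reference program needs before it can benchmark clinical
cases for which no closed form exists.

A miniature discretisation study on clinical-like cases:

```r
cases <- lapply(1:3, function(i)
  make_clinical_like_case(clinical_case_spec(n_lesions = 4, seed = derive_seed(11, i)),
                          case_name = sprintf("case%02d", i)))
res <- run_study(cases, study_config(st = 1, dg = c(1, 2, 3), seed = 11))
res
```

```
study_result: 12 targets, perturbations: DG_2mm, DG_3mm
  DG_2mm: Spearman rho 0.875 (p 9.33e-24), fit NRMSE 0.080
  DG_3mm: Spearman rho 0.872 (p 2.2e-23), fit NRMSE 0.078
```

Coarse dose grids underestimate small isodose volumes: the fitted DG-2mm
ratio curve crosses 0.95 around 2 cm³ and approaches 1 for large volumes,
while the 3-mm grid needs roughly 10 cm³ to reach the same agreement. The
per-group signed-rank tables (`res$index_stats`) show the same picture in
the indices: GI is the most DG-sensitive quantity, D95 the least.

There is also a thin command-line front end:

```sh
inst/cli/srsdvh generate --out bundles/gt --diameters 3,7,10,15,20 --n 50 --seed 1
inst/cli/srsdvh validate --bundle bundles/gt
inst/cli/srsdvh study --bundle cases/case01,cases/case02 --st 1,1.5,2 --dg 1,2,3 --out report/
```

## Vignette

`vignettes/methods.Rmd` documents the dose model, the contouring and
end-capping conventions, the two interpolants and why validation and study
deliberately use different ones, the statistics, and the generator's scope
and limitations.
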