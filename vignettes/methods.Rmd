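---
title: "Methods: DVH accuracy QA under slice-thickness and dose-grid discretisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DVH accuracy QA under slice-thickness and dose-grid discretisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsdvh)
```

## The problem

Dose-volume histograms (DVHs) and the plan-quality indices derived from them
(D95, V30Gy, the Paddick conformity index CI and the gradient index GI) are
the quantities on which intracranial stereotactic radiosurgery (SRS) plans
are accepted or rejected. All of them are computed from two discretised
objects: a stack of planar contours drawn on CT slices of thickness ST, and
a dose matrix sampled on a grid of resolution DG. For the millimetre-scale
targets and steep gradients of SRS, both discretisations bias the result.
`srsdvh` provides a self-contained QA pipeline for quantifying these biases:
analytic phantoms whose volumes and isodose volumes are known in closed
form, a contour-based volume engine, a mini-voxel DVH engine, and the
statistical machinery of an ST/DG perturbation study. It is aimed at medical
physicists commissioning the DVH tool of an SRS platform and at method
developers who need a fully analytic ground truth.

## The dose model

Each target carries a radial dose model emulating a VMAT SRS plan
normalised so that 100% of the prescription sits on the target surface
(radius $R$, mm):

$$ D(r) = b + (100 - b)\,\min\!\left(2^{-(r-R)/g},\, \kappa\right) $$

in % of prescription, with $g$ the distance (mm) over which the dose halves
beyond the surface, $b$ a far-field bath and $\kappa$ the interior cap
ratio. Defaults are $g = 3$ mm (typical intracranial VMAT falloff,
producing gradient indices between about 8 for 6-mm targets and 1.7 for
30-mm targets, i.e. the clinical range), $b = 0$ and $\kappa = 1.25$ (an
interior hot spot of 125%, typical of SRS plans prescribed to a peripheral
isodose). Isodose radii are closed-form for every level up to the cap,
$r_L = R + g \log_2(100/L)$, which makes every isodose volume an exact
sphere volume — the package's ground truth.

Two properties of this form matter numerically. First, it is a *single*
exponential law through the 100% level, so the dose gradient is continuous
at every evaluated isodose level; a model with a flat interior plateau has
a gradient kink exactly at the prescription level, and any interpolated
sampling of it mislocates the V100% surface by a large, systematic margin
(we measured 13-27% for 3-mm targets — an artefact of the model, not of
the engine). Second, the interior cap only introduces a kink at 125%,
above every level the pipeline evaluates.

## Structure geometry and volumes

Structures are stacks of closed planar polygons. Analytic spheres are
contoured the way a clinician would: on every slice position intersecting
the sphere, a 64-vertex regular polygon inscribed in the circle
$\sqrt{R^2 - (z - c_z)^2}$ evaluated at the slice position (no slab
averaging). Containment is even-odd with boundary points counting as
inside, so multi-ring slices describe annuli. The slab convention assigns a
contour at $z_c$ to the slab $[z_c - ST/2, z_c + ST/2)$; the first and last
contours extend half a slice (half-slab end-capping). No interslice contour
interpolation is performed; reslicing analytic shapes regenerates contours
exactly from the shape equation on the new ladder (common lattice origin),
and imported polygon stacks take the nearest original contour, ties toward
the inferior slice.

Voxels are supersampled hierarchically: voxels larger than 1 mm^3 are split
into equal sub-voxels no larger than that, and sub-voxels are further split
until a mini-voxel is at most 1/27 of the dose-voxel volume. For the
default 0.6 x 0.6 x 1 mm CT against a 1-mm dose grid this yields 3 x 3 x 3
sub-points per CT voxel.

Volumes are reported with one of two end-capping conventions:

* **parabolic** (default, the reporting convention): the supersampled
  per-slice cross-section areas $A(z)$ are integrated with a
  locally-quadratic rule, and the caps beyond the outermost contours are
  closed by extrapolating a quadratic through the three outermost areas to
  its zero crossing (clipped to one slice). $A(z)$ is exactly quadratic
  for spheres and ellipsoids, so the z-integration is exact for them and
  the residual error is the in-plane sampling of the 64-gon (a -0.16%
  area bias plus sub-point noise).
* **half-slab**: occupancy fractions times voxel volume. This is the
  convention used by the DVH path (it is the one consistent with slab
  membership of mini-voxels), but as a volume estimator its z-quantisation
  error for a 3-mm sphere on 1-mm slices is ~4% on average and ~11% worst
  case — an order larger than the in-plane error. The package therefore
  reports parabolic volumes; the half-slab option remains for studying
  exactly this convention effect.

A note on the boundary tie rule: because boundary points count as inside,
a polygon whose edges coincide exactly with the sub-point lattice gains one
ring of sub-points (measure zero for generic placements; visible only in
deliberately aligned fixtures).

## Isodose volumes and the DVH engine

Isodose volumes are measured by mini-voxel sampling inside an evaluation
region — the analytic 25%-isodose sphere for ground-truth bundles, or a
target bounding sphere expanded by a 1.5-cm shell for clinical-like cases
(the shell isolates each lesion from its neighbours' prescription
isodoses; lesion placement guarantees no neighbour's 100% isodose enters
another's shell). A mini-voxel counts toward $V_L$ when its interpolated
dose is at or above $L$ (inclusive threshold; "receiving the prescription
dose" V30Gy is likewise implemented as >= 100%).

Two interpolants are provided, and their separation is deliberate:

* **tricubic Catmull-Rom** (`interp = "cubic"`, default of the validation
  path): third-order accurate, locates the steep exponential falloff to a
  small fraction of a voxel. With it, 3-mm-target V100% volumes on a 1-mm
  grid are recovered with ~1% mean and <4% maximum error over randomly
  placed targets — the accuracy level a reference ("in-house") program
  must reach before it can serve as a clinical benchmark.
* **trilinear** (`interp = "linear"`, default of the perturbation study):
  the plain interpolant of a TPS DVH tool. Its leading error term follows
  the field's curvature, which for a radial dose peak is negative — so it
  systematically *underestimates* small isodose volumes, increasingly so
  on coarser grids. This is precisely the discretisation bias the ST/DG
  study is designed to expose, and with it the study reproduces the
  clinical pattern: V-ratios below 1 that rise toward 1 with volume,
  underestimated V30Gy and D95, overestimated CI and GI on coarse grids,
  GI the most and D95 the least sensitive index.

Cumulative DVHs histogram mini-voxel doses from the top with a 0.1% bin
width; D95 interpolates linearly within bins. The Paddick CI uses the
parabolic structure volume as TV, with PIV and TV-within-PIV from the same
mini-voxel pass restricted to the evaluation region; TV_PIV is clamped to
min(TV, PIV) to absorb the (sub-mini-voxel) inconsistency between the
CT-based and dose-based samplings.

## Phantoms

`make_ground_truth_bundle()` builds the analytical commissioning dataset:
by default 50 spheres per diameter with centres uniformly offset within one
CT voxel (seeded), contoured on the 0.6 x 0.6 x 1 mm CT ladder, each with
its radial dose model, its 25%-isodose evaluation sphere, and a manifest of
closed-form nominal values that never touch the rasteriser. Dose matrices
are materialised lazily per target; a coarser DG means re-evaluating the
analytic model at the coarser voxel centres on the common origin —
emulating a TPS recalculation rather than smoothing the fine grid.

`make_clinical_like_case()` builds multi-lesion cases: lesions are spheres
with low-order azimuthal harmonic perturbations (seeded; diameter labels
mean maximum axial diameter), the per-lesion dose plateau covers the whole
lesion (so prescription coverage is complete by construction), lesions
combine by voxelwise maximum (keeping per-lesion closed forms exact while
separated) plus a smooth Gaussian low-dose bath (5% peak, 60-mm width).
What these cases do *not* emulate: MLC-sculpted dose asymmetries, Monte
Carlo dose noise, CT density heterogeneity, or truly irregular (concave)
target shapes. Passing tests on them demonstrates correct discretisation
behaviour of the engines, not clinical equivalence to any patient cohort.

## The perturbation study

`run_study()` evaluates every target at the reference discretisation
(ST = DG = 1 mm) and at the perturbed settings (default DG 2 and 3 mm at
reference ST; ST 1.5 and 2 mm at reference DG). Because the analytic dose
is unchanged by reslicing, the ST effect flows only through structure
discretisation and DVH sampling; V_dose ratios under ST changes are
identically 1 and the corresponding rank correlation is the documented
degenerate case — the synthetic analogue of the weak, noise-dominated ST
dependence seen clinically.

Statistics follow the field's conventions:

* V_dose ratios (eval/ref) against reference volume: Spearman rank
  correlation (exact permutation p for n <= 9, t approximation beyond) and
  a power-law fit $y = a x^b + c$. The fit profiles $b$ on a grid (the
  model is linear in $a, c$ for fixed $b$), refines with `optimize` and a
  Levenberg-Marquardt polish, and reports NRMSE = RMSE / range(y)
  (defined as 0 for a degenerate range). Parameter recovery on noise-free
  data is at the 1e-6 level.
* Paired index comparisons: two-sided Wilcoxon signed-rank. Zero
  differences are dropped; for up to 25 nonzero pairs the exact null
  distribution is enumerated by dynamic programming on doubled midranks
  (exact even under ties — `stats::wilcox.test` refuses exactness there,
  which is why the distribution is built in-package; it remains the
  implementation for the large-sample normal approximation). No
  multiple-testing correction is applied; p-values are reported raw.
* Paired effect size d = mean/sd of differences, and required sample size
  from the paired normal approximation inflated by the signed-rank
  asymptotic relative efficiency (0.955), rounded up.

## Numerical choices and degenerate inputs

* Boundary points are inside; polygon orientation is normalised to
  counter-clockwise; degenerate polygons (<3 distinct vertices) error.
* Dose lookups outside the grid hull clamp to the nearest voxel and are
  counted and warned about.
* Isodose levels at or below the bath error (the region is unbounded);
  levels above the capped maximum return volume 0.
* A constant ratio set makes Spearman's rho undefined; it is reported as 0
  with a warning. All-zero paired differences give p = 1 with a note.
* Every random draw derives from one master seed through a fixed stream
  split (`derive_seed`), keeping all seeds in 32-bit range; identical
  spec + seed reproduces bundles and studies bit for bit.

## Problem sizes used by the shipped tests and scripts

The test-suite uses reduced fixtures (a handful of spheres or lesions per
case) chosen so each property is still sharply testable; the acceptance
script regenerates the full commissioning setup — 50 spheres per diameter
in {3, 7, 10, 15, 20} mm and 15 clinical-like three-lesion cases spanning
the 6-30 mm groups — which completes in a few minutes on one CPU.

## Known limitations

* No DICOM I/O: cases are exchanged in a documented plain-text JSON/CSV
  layout carrying the same geometric information (patient coordinates,
  frame of reference, lattice origins). External DICOM data must be
  converted into that layout.
* The radial dose model is isotropic by default (anisotropy scales exist)
  and cannot represent concave dose distributions.
* Evaluation shells are bounding-sphere based; for extremely elongated
  lesions they are wider than a true morphological expansion.
* The clinical-like generator's irregularity is in-plane only; polar
  perturbations would require a genuinely 3-D harmonic model.
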