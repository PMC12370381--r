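#' Seed streams derived from one master seed
#'
#' Every stochastic draw in the package derives its seed from the master
#' seed by a fixed multiplicative-hash stream split, keeping results inside
#' the 32-bit integer range.
#'
#' @param master master seed (integer).
#' @param stream stream index (integer >= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(master, stream) {
  as.integer((as.double(master) * 69069 + as.double(stream) * 40503) %% 2147483647)
}

#' Analytical ground-truth phantom bundle
#'
#' Builds the analytical commissioning dataset: for each requested diameter,
#' `n_per_diameter` spheres with centres uniformly offset within one CT
#' voxel, contoured on the CT slice ladder, each with (i) a radial
#' [dose_model()] whose 100% isodose coincides with the sphere surface,
#' (ii) an analytic 25%-isodose evaluation sphere, and (iii) a manifest row
#' of closed-form nominal values (`pi D^3/6` volume, analytic V100%, V50%,
#' 25% radius) that never touch the rasteriser. Targets live on a common CT
#' lattice but are laid out on well-separated cell centres; dose matrices
#' are materialised lazily per target with [target_dose()].
#'
#' @param diameters sphere diameters, mm (within 3-30 mm).
#' @param n_per_diameter spheres per diameter (default 50).
#' @param ct_spacing CT voxel size, mm (default 0.6 x 0.6 x 1).
#' @param dose_spacing dose-grid resolution, mm (default 1 mm isotropic).
#' @param g,peak_ratio,bath dose model parameters, see [dose_model()].
#' @param prescription prescription dose, Gy.
#' @param n_vertices contour vertices per circle.
#' @param seed master seed for the centre offsets.
#' @return object of class `phantom_bundle`: `ct_grid`, `dose_spacing`,
#'   `targets` (list of per-target records: `structure`, `model`, `region`,
#'   `diameter`), `manifest` (data.frame), `prescription`, `seed`.
#' @export
make_ground_truth_bundle <- function(diameters = c(3, 7, 10, 15, 20),
                                     n_per_diameter = 50,
                                     ct_spacing = c(0.6, 0.6, 1),
                                     dose_spacing = c(1, 1, 1),
                                     g = 3, peak_ratio = 1.25, bath = 0,
                                     prescription = 30, n_vertices = 64L,
                                     seed = 1) {
  stopifnot(all(diameters >= 3), all(diameters <= 30), n_per_diameter >= 1)
  n_tot <- length(diameters) * n_per_diameter
  # cell pitch: largest evaluation sphere plus margin, snapped to CT lattice
  r25_max <- max(diameters) / 2 + 2 * g
  pitch <- ceiling((2 * r25_max + 6))
  n_side <- ceiling(sqrt(n_tot))
  extent <- c(n_side, n_side, 1) * pitch
  dims <- ceiling(extent / ct_spacing) + 8
  ct_grid <- voxel_grid(c(0, 0, 0), ct_spacing, dims)
  slice_z <- grid_axes(ct_grid)$z
  targets <- vector("list", n_tot)
  rows <- vector("list", n_tot)
  i <- 0L
  for (D in diameters) {
    R <- D / 2
    for (j in seq_len(n_per_diameter)) {
      i <- i + 1L
      old <- .Random.seed_save(); set.seed(derive_seed(seed, i))
      offset <- stats::runif(3) * ct_spacing
      .Random.seed_restore(old)
      cell <- c(((i - 1L) %% n_side), ((i - 1L) %/% n_side), 0)
      center <- cell * pitch + pitch / 2 + offset
      nm <- sprintf("sphere_D%g_%03d", D, j)
      struct <- sphere_structure(center, D, slice_z, st = ct_spacing[3],
                                 name = nm, n_vertices = n_vertices)
      model <- dose_model(R = R, g = g, plateau = 100, bath = bath,
                          peak_ratio = peak_ratio, center = center)
      region <- eval_region_sphere(center, isodose_radius(25, model),
                                   name = paste0(nm, "_eval25"))
      targets[[i]] <- list(structure = struct, model = model, region = region,
                           diameter = D)
      rows[[i]] <- data.frame(
        target = nm, diameter = D,
        volume_cm3 = sphere_volume(D),
        v100_cm3 = analytic_isodose_volume(100, model),
        v50_cm3 = analytic_isodose_volume(50, model),
        r25_mm = isodose_radius(25, model))
    }
  }
  structure(list(kind = "ground_truth", ct_grid = ct_grid,
                 dose_spacing = rep_len(as.numeric(dose_spacing), 3L),
                 targets = targets, manifest = do.call(rbind, rows),
                 prescription = prescription, seed = seed),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("phantom_bundle (%s): %d target(s), CT %s mm, dose %s mm, Rx %g Gy\n",
              x$kind, length(x$targets),
              paste(signif(x$ct_grid$spacing, 3), collapse = "x"),
              paste(signif(x$dose_spacing, 3), collapse = "x"),
              x$prescription))
  invisible(x)
}

#' Materialise the dose matrix around one bundle target
#'
#' Samples the target's analytic dose model (and any sibling models plus
#' the case bath for clinical-like bundles) on a lattice covering the
#' target's evaluation region. `dg` overrides the bundle's dose-grid
#' resolution: coarser values emulate recalculating the plan on a coarser
#' dose grid, i.e. the analytic model is re-evaluated at the coarser voxel
#' centres with the common origin preserved.
#'
#' @param bundle a `phantom_bundle`.
#' @param i target index.
#' @param dg dose-grid resolution, mm (scalar or numeric(3)).
#' @return a [dose_grid()].
#' @export
target_dose <- function(bundle, i, dg = bundle$dose_spacing) {
  t <- bundle$targets[[i]]
  dg <- rep_len(as.numeric(dg), 3L)
  bb <- region_bbox(t$region)
  full <- voxel_grid(bundle$ct_grid$origin, dg,
                     ceiling((bundle$ct_grid$spacing * bundle$ct_grid$dims) / dg) + 1)
  sub <- crop_grid(full, bb$lo, bb$hi, pad = 3 * dg + 3)
  models <- if (identical(bundle$kind, "clinical_like"))
    lapply(bundle$targets, `[[`, "model") else list(t$model)
  sample_dose_grid(models, sub, prescription = bundle$prescription,
                   bath_field = bundle$bath_field)
}

#' Clinical-like multi-lesion case specification
#'
#' @param n_lesions number of lesions.
#' @param diameters per-lesion maximum axial diameter labels, mm (subset of
#'   6, 10, 15, 20, 25, 30); recycled to `n_lesions`.
#' @param irregularity amplitude scale of the azimuthal shape harmonics.
#' @param prescription prescription dose, Gy (default 30 Gy in 5 fractions).
#' @param shell_cm evaluation shell width, cm.
#' @param min_sep_factor lesion centres must be separated by at least this
#'   multiple of the sum of their 50%-isodose radii (and always far enough
#'   that no shell contains a neighbour's prescription isodose).
#' @param g,peak_ratio dose model parameters.
#' @param bath_level,bath_sigma Gaussian low-dose bath: peak %, width mm.
#' @param seed case seed.
#' @return object of class `clinical_case_spec`.
#' @export
clinical_case_spec <- function(n_lesions = 3,
                               diameters = c(6, 10, 15, 20, 25, 30),
                               irregularity = 0.06, prescription = 30,
                               shell_cm = 1.5, min_sep_factor = 1,
                               g = 3, peak_ratio = 1.25,
                               bath_level = 5, bath_sigma = 60, seed = 1) {
  stopifnot(n_lesions >= 1, all(diameters %in% c(6, 10, 15, 20, 25, 30)))
  structure(list(n_lesions = n_lesions,
                 diameters = rep_len(diameters, n_lesions),
                 irregularity = irregularity, prescription = prescription,
                 shell_cm = shell_cm, min_sep_factor = min_sep_factor,
                 g = g, peak_ratio = peak_ratio, bath_level = bath_level,
                 bath_sigma = bath_sigma, seed = seed),
            class = "clinical_case_spec")
}

#' Generate a clinical-like multi-lesion case
#'
#' Lesions are irregular blobs ([blob_structure()]) with seeded low-order
#' azimuthal harmonics; each carries a radial dose model whose 100% isodose
#' is the lesion bounding sphere, so prescription coverage of the target is
#' complete by construction (>= 95% after discretisation). The case dose is
#' the voxelwise maximum of the per-lesion models plus a smooth Gaussian
#' low-dose bath. Lesion centres are drawn within a cranial-sized box under
#' the separation constraint (bounded retries), guaranteeing each 1.5-cm
#' evaluation shell excludes every other lesion's prescription isodose.
#'
#' @param spec a [clinical_case_spec()].
#' @param ct_spacing CT voxel size, mm.
#' @param dose_spacing dose-grid resolution, mm.
#' @param case_name label used in structure names.
#' @return a `phantom_bundle` of kind `"clinical_like"` whose manifest
#'   carries the closed-form per-lesion isodose volumes (exact when lesions
#'   are separated and the bath stays below the level).
#' @export
make_clinical_like_case <- function(spec, ct_spacing = c(0.6, 0.6, 1),
                                    dose_spacing = c(1, 1, 1),
                                    case_name = "case") {
  stopifnot(inherits(spec, "clinical_case_spec"))
  n <- spec$n_lesions
  Rs <- spec$diameters / 2
  r50 <- Rs + spec$g
  shell_mm <- spec$shell_cm * 10
  # minimum pairwise separations
  sep <- function(i, j) max(spec$min_sep_factor * (r50[i] + r50[j]),
                            Rs[i] + shell_mm + Rs[j] + 1,
                            Rs[j] + shell_mm + Rs[i] + 1)
  box <- max(120, 2 * (max(Rs) + shell_mm) + 20)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, 1L))
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(400L)) {
      cand <- stats::runif(3, max(Rs) + shell_mm / 2,
                           box - max(Rs) - shell_mm / 2)
      ok <- i == 1L || all(vapply(seq_len(i - 1L), function(j)
        sqrt(sum((cand - centers[j, ])^2)) >= sep(i, j), TRUE))
      if (ok) { centers[i, ] <- cand; break }
    }
    if (!ok) stop("infeasible lesion separation constraint")
  }
  dims <- ceiling(c(box, box, box) / ct_spacing) + 8
  ct_grid <- voxel_grid(c(0, 0, 0), ct_spacing, dims)
  slice_z <- grid_axes(ct_grid)$z
  targets <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, 100L + i))
    nk <- 2L
    harm <- list(k = 2:(1 + nk),
                 a = stats::runif(nk, 0, spec$irregularity),
                 psi = stats::runif(nk, 0, 2 * pi))
    nm <- sprintf("%s_lesion%02d_D%g", case_name, i, spec$diameters[i])
    struct <- blob_structure(centers[i, ], spec$diameters[i], slice_z,
                             st = ct_spacing[3], harmonics = harm, name = nm)
    model <- dose_model(R = Rs[i], g = spec$g, plateau = 100, bath = 0,
                        peak_ratio = spec$peak_ratio, center = centers[i, ])
    region <- eval_region_sphere(centers[i, ], Rs[i] + shell_mm,
                                 name = paste0(nm, "_shell"))
    targets[[i]] <- list(structure = struct, model = model, region = region,
                         diameter = spec$diameters[i])
    rows[[i]] <- data.frame(
      target = nm, diameter = spec$diameters[i],
      volume_cm3 = NA_real_,     # irregular: no closed form; see rasteriser
      v100_cm3 = analytic_isodose_volume(100, model),
      v50_cm3 = analytic_isodose_volume(50, model),
      r25_mm = isodose_radius(25, model))
  }
  structure(list(kind = "clinical_like", ct_grid = ct_grid,
                 dose_spacing = rep_len(as.numeric(dose_spacing), 3L),
                 targets = targets, manifest = do.call(rbind, rows),
                 prescription = spec$prescription, seed = spec$seed,
                 bath_field = list(level = spec$bath_level,
                                   center = rep(box / 2, 3),
                                   sigma = spec$bath_sigma),
                 spec = spec),
            class = "phantom_bundle")
}
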