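#' Radial dose model parameters
#'
#' Closed-form dose model for a single spherical-ish target, emulating the
#' steep falloff of a VMAT SRS plan: the dose follows a single exponential
#' law in the radial distance, halving every `g` mm beyond the target
#' surface at radius `R`, continued inward and capped at `peak_ratio` times
#' the surface dose (real SRS plans carry an interior hot spot of roughly
#' 110-140% of prescription; the cap keeps the interior finite and the
#' gradient continuous at every evaluated isodose level):
#'
#' `dose(r) = bath + (plateau - bath) * min(2^(-(r - R)/g), peak_ratio)`
#'
#' so `dose(R) = plateau` (100% of prescription at the target surface),
#' `dose(R + g) = 50%` and `dose(R + 2g) = 25%` when `bath = 0`. Anisotropy
#' scale factors stretch the model per axis: the radial coordinate of a
#' point p is `||(p - center) / scales||`.
#'
#' @param R target radius, mm (> 0).
#' @param g distance beyond R at which dose falls to 50% of the surface
#'   dose, mm (> 0); default 3 mm, typical of intracranial VMAT falloff.
#' @param plateau dose at the target surface, % of prescription.
#' @param bath far-field dose floor, % (must be < plateau).
#' @param peak_ratio interior cap as a multiple of `plateau` (>= 1).
#' @param scales numeric(3) per-axis anisotropy factors (> 0).
#' @param center numeric(3), mm; the target centre.
#' @return object of class `dose_model`.
#' @export
dose_model <- function(R, g = 3, plateau = 100, bath = 0, peak_ratio = 1.25,
                       scales = c(1, 1, 1), center = c(0, 0, 0)) {
  stopifnot(R > 0, g > 0, plateau > bath, bath >= 0, peak_ratio >= 1,
            all(scales > 0))
  structure(list(R = R, g = g, plateau = plateau, bath = bath,
                 peak_ratio = peak_ratio, scales = rep_len(as.numeric(scales), 3L),
                 center = as.numeric(center)),
            class = "dose_model")
}

#' @export
print.dose_model <- function(x, ...) {
  cat(sprintf("dose_model: R %g mm, 50%% falloff %g mm, surface %g%%, cap %g%%, bath %g%%\n",
              x$R, x$g, x$plateau, x$plateau * x$peak_ratio, x$bath))
  invisible(x)
}

#' Dose at radial distance r
#'
#' @param r radial distance(s) from the target centre, mm (>= 0).
#' @param params a [dose_model()].
#' @return dose in % of prescription; continuous, monotone non-increasing,
#'   strictly decreasing beyond the interior cap radius.
#' @examples
#' m <- dose_model(R = 1.5, g = 3)
#' radial_dose(1.5, m)        # 100
#' radial_dose(4.5, m)        # 50
#' radial_dose(7.5, m)        # 25
#' @export
radial_dose <- function(r, params) {
  stopifnot(inherits(params, "dose_model"), all(r >= 0))
  params$bath + (params$plateau - params$bath) *
    pmin(2^(-(r - params$R) / params$g), params$peak_ratio)
}

#' Radius of an isodose level, mm
#'
#' Inverts the radial model: `r_L = R + g * log2((plateau - bath)/(level - bath))`,
#' valid for `bath < level <= plateau * peak_ratio` (levels above the surface
#' dose map inside the target; the interior cap bounds them).
#'
#' @param level isodose level, % of prescription.
#' @param params a [dose_model()].
#' @return radius, mm (0 if the level exceeds the capped maximum).
#' @export
isodose_radius <- function(level, params) {
  stopifnot(inherits(params, "dose_model"))
  if (level <= params$bath)
    stop("isodose level at or below the dose bath is unbounded")
  top <- params$bath + (params$plateau - params$bath) * params$peak_ratio
  if (level > top) return(0)
  max(params$R + params$g *
        log2((params$plateau - params$bath) / (level - params$bath)), 0)
}

#' Closed-form isodose volume, cm^3
#'
#' Volume enclosed by the `level`% isodose surface of the analytic model:
#' `(4/3) pi r_L^3` times the product of the anisotropy scales.
#'
#' @inheritParams isodose_radius
#' @return volume in cm^3.
#' @examples
#' m <- dose_model(R = 1.5, g = 3)
#' analytic_isodose_volume(100, m) * 1000  # 14.137 mm^3
#' analytic_isodose_volume(50, m) * 1000   # 381.7 mm^3
#' @export
analytic_isodose_volume <- function(level, params) {
  rl <- isodose_radius(level, params)
  (4 / 3) * pi * rl^3 * prod(params$scales) / 1000
}

#' Analytic nominal volume of a sphere, cm^3
#' @param diameter mm.
#' @return `pi D^3 / 6` in cm^3.
#' @export
sphere_volume <- function(diameter) pi * diameter^3 / 6 / 1000

# Effective radial distance of points (n x 3 mm) under the model's
# anisotropy scaling.
model_radius <- function(points, params) {
  d <- sweep(points, 2, params$center)
  d <- sweep(d, 2, params$scales, `/`)
  sqrt(rowSums(d^2))
}

#' Dose matrix on a voxel lattice
#'
#' A `dose_grid` couples a [voxel_grid()] with absolute dose values (Gy) and
#' the prescription dose used for normalisation (all indices in the package
#' work on the normalised % scale, where 100% is the prescription).
#'
#' @param grid a [voxel_grid()] (spacing is the dose-grid resolution DG).
#' @param values 3-D array of dose, Gy, with `dim == grid$dims`.
#' @param prescription prescription dose, Gy (> 0).
#' @return object of class `dose_grid`.
#' @export
dose_grid <- function(grid, values, prescription) {
  stopifnot(inherits(grid, "voxel_grid"), prescription > 0)
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), as.integer(grid$dims)))
    stop("dose value array does not match the grid dims")
  if (any(values < 0)) stop("dose values must be non-negative")
  structure(list(grid = grid, values = values, prescription = prescription),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %d x %d x %d @ %.3g x %.3g x %.3g mm, Rx %g Gy, max %.1f%%\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$grid$spacing[1], x$grid$spacing[2], x$grid$spacing[3],
              x$prescription, 100 * max(x$values) / x$prescription))
  invisible(x)
}

#' Sample analytic dose models onto a lattice
#'
#' Evaluates one or more radial models (and an optional smooth Gaussian
#' background bath) at the voxel centres of `grid`, combining sources by
#' voxelwise maximum so each lesion's closed-form isodose volumes remain
#' exact while lesions are separated. This is also the "recalculation"
#' semantics of the dose-grid perturbation study: changing DG means
#' re-evaluating the analytic model at coarser voxel centres.
#'
#' @param models a [dose_model()] or list of them.
#' @param grid the target [voxel_grid()].
#' @param prescription prescription dose, Gy (100% level).
#' @param bath_field optional list `(level, center, sigma)`: a Gaussian
#'   low-dose bath `level * exp(-||p - center||^2 / (2 sigma^2))` in %.
#' @return a [dose_grid()].
#' @export
sample_dose_grid <- function(models, grid, prescription = 30,
                             bath_field = NULL) {
  if (inherits(models, "dose_model")) models <- list(models)
  ax <- grid_axes(grid)
  pts <- cbind(rep(ax$x, times = grid$dims[2] * grid$dims[3]),
               rep(rep(ax$y, each = grid$dims[1]), times = grid$dims[3]),
               rep(ax$z, each = grid$dims[1] * grid$dims[2]))
  pct <- rep(0, nrow(pts))
  for (m in models)
    pct <- pmax(pct, radial_dose(model_radius(pts, m), m))
  if (!is.null(bath_field)) {
    d2 <- rowSums(sweep(pts, 2, bath_field$center)^2)
    pct <- pmax(pct, bath_field$level * exp(-d2 / (2 * bath_field$sigma^2)))
  }
  dose_grid(grid, array(pct / 100 * prescription, grid$dims), prescription)
}
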