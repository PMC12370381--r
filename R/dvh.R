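#' Interpolated dose lookup
#'
#' Continuous dose at arbitrary points from a [dose_grid()], normalised to %
#' of prescription. Two interpolants are available: `"cubic"` (default),
#' tricubic Catmull-Rom convolution, which locates steep SRS gradients to
#' third order and is the package's reference for isodose volumes; and
#' `"linear"`, classical trilinear interpolation of the 8 surrounding voxel
#' centres. Points outside the lattice hull are clamped to the nearest voxel
#' and counted in the `n_clamped` attribute.
#'
#' @param dose a [dose_grid()].
#' @param points n x 3 matrix of positions, mm.
#' @param interp `"cubic"` or `"linear"`.
#' @return numeric vector of doses in % of prescription, with attribute
#'   `n_clamped`.
#' @export
dose_at <- function(dose, points, interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  stopifnot(inherits(dose, "dose_grid"))
  points <- matrix(as.numeric(points), ncol = 3)
  method <- if (interp == "linear") 0L else 1L
  if (interp == "cubic" && any(dose$grid$dims < 4L)) method <- 0L
  res <- cpp_interp3(as.numeric(dose$values), dose$grid$dims, dose$grid$origin,
                     dose$grid$spacing, points[, 1], points[, 2], points[, 3],
                     method)
  out <- res$values / dose$prescription * 100
  if (res$n_clamped > 0)
    warning(sprintf("%d dose lookup(s) outside the grid hull were clamped", res$n_clamped))
  attr(out, "n_clamped") <- res$n_clamped
  out
}

#' Trilinear dose lookup (% of prescription)
#'
#' Convenience wrapper for [dose_at()] with the trilinear interpolant.
#' @inheritParams dose_at
#' @param p n x 3 matrix (or length-3 vector) of positions, mm.
#' @export
trilinear_dose <- function(dose, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  dose_at(dose, p, interp = "linear")
}

#' Evaluation region around a target
#'
#' Isodose volumes of a target are measured inside an evaluation region that
#' contains the target and excludes dose from neighbouring lesions: either a
#' sphere (the analytic 25%-isodose evaluation volume of the ground-truth
#' bundles, or a target bounding sphere expanded by the shell width) or an
#' arbitrary contoured structure.
#'
#' @param center numeric(3) mm (sphere regions).
#' @param radius mm (sphere regions).
#' @param struct an [rt_structure()] (contoured regions).
#' @param name label.
#' @return object of class `eval_region`.
#' @export
eval_region_sphere <- function(center, radius, name = "eval") {
  stopifnot(radius > 0)
  structure(list(type = "sphere", center = as.numeric(center), radius = radius,
                 name = name), class = "eval_region")
}

#' @rdname eval_region_sphere
#' @export
eval_region_structure <- function(struct, name = struct$name) {
  stopifnot(inherits(struct, "rt_structure"))
  structure(list(type = "structure", struct = struct, name = name),
            class = "eval_region")
}

#' Shell-style evaluation region for a target with an analytic shape
#'
#' The target's bounding sphere expanded by `width_cm`; it fully contains
#' the target and, given adequate lesion separation, excludes neighbouring
#' prescription isodoses.
#'
#' @param target an [rt_structure()] with analytic descriptor.
#' @param width_cm shell width, cm (default 1.5).
#' @export
evaluation_shell <- function(target, width_cm = 1.5) {
  a <- target$analytic
  if (is.null(a)) stop("evaluation_shell requires an analytic target")
  eval_region_sphere(a$center, a$radius + width_cm * 10,
                     name = paste0(target$name, "_shell"))
}

region_bbox <- function(region) {
  if (region$type == "sphere")
    list(lo = region$center - region$radius, hi = region$center + region$radius)
  else structure_bbox(region$struct)
}

region_contains <- function(region, points) {
  if (region$type == "sphere") {
    d <- sweep(points, 2, region$center)
    rowSums(d^2) <= region$radius^2
  } else inside_structure(points, region$struct)
}

#' Is a point inside a contoured structure?
#'
#' Slab z-assignment (contour at zc governs `[zc - st/2, zc + st/2)`) plus
#' in-plane even-odd containment; the convention shared with
#' [rasterize_structure()].
#'
#' @param points n x 3 matrix, mm.
#' @param struct an [rt_structure()].
#' @return logical vector.
#' @export
inside_structure <- function(points, struct) {
  points <- matrix(as.numeric(points), ncol = 3)
  zs <- contour_z(struct)
  uz <- unique(zs)
  slab <- slab_index(points[, 3], uz, struct$st)
  out <- logical(nrow(points))
  for (g in seq_along(uz)) {
    hit <- which(!is.na(slab) & slab == g)
    if (!length(hit)) next
    parity <- integer(length(hit))
    for (cc in struct$contours[abs(zs - uz[g]) < 1e-9])
      parity <- cpp_accumulate_ring(parity, points[hit, 1], points[hit, 2],
                                    cc$vertices, 1e-9)
    out[hit] <- parity == 1L
  }
  out
}

# Enumerate mini-voxel centre positions for the dose-grid voxels whose
# centres lie within the region bbox (+pad), chunked by z-layer. Calls
# fun(points_matrix, mini_volume_cm3) for each chunk and concatenates.
map_mini_points <- function(dose, region, scheme, fun, pad = 0) {
  bb <- region_bbox(region)
  sub <- crop_grid(dose$grid, bb$lo, bb$hi, pad = pad + dose$grid$spacing)
  ax <- grid_axes(sub)
  f <- scheme$factor
  sp <- sub$spacing
  mx <- sort(as.vector(outer(ax$x, sub_offsets(sp[1], f[1]), `+`)))
  my <- sort(as.vector(outer(ax$y, sub_offsets(sp[2], f[2]), `+`)))
  mz <- sort(as.vector(outer(ax$z, sub_offsets(sp[3], f[3]), `+`)))
  mini_vol <- prod(sp / f) / 1000
  plane <- cbind(rep(mx, times = length(my)), rep(my, each = length(mx)))
  out <- vector("list", length(mz))
  for (k in seq_along(mz)) {
    pts <- cbind(plane, mz[k])
    out[[k]] <- fun(pts, mini_vol)
  }
  out
}

#' Isodose volumes inside an evaluation region
#'
#' Volume of the mini-voxels inside `region` whose interpolated dose is at
#' or above each level (inclusive threshold). Mini-voxels subdivide the
#' dose-grid voxels per `scheme`; dose is interpolated per [dose_at()].
#'
#' @param dose a [dose_grid()].
#' @param levels isodose level(s), % of prescription (> 0).
#' @param region an `eval_region`.
#' @param scheme [supersampling_scheme()]; defaults to the two-stage rule on
#'   the dose spacing.
#' @param interp interpolant passed to [dose_at()].
#' @return named numeric vector of volumes, cm^3 (one per level).
#' @export
isodose_volumes <- function(dose, levels, region,
                            scheme = supersampling_scheme(dose$grid$spacing,
                                                          dose$grid$spacing),
                            interp = "cubic") {
  stopifnot(all(levels > 0))
  n_in <- 0L
  chunks <- map_mini_points(dose, region, scheme, function(pts, mv) {
    keep <- region_contains(region, pts)
    if (!any(keep)) return(numeric(length(levels)))
    n_in <<- n_in + sum(keep)
    d <- suppressWarnings(dose_at(dose, pts[keep, , drop = FALSE], interp))
    vapply(levels, function(L) sum(d >= L), 0)
  })
  if (n_in == 0L) stop("empty evaluation region")
  counts <- Reduce(`+`, chunks)
  mini_vol <- prod(dose$grid$spacing / scheme$factor) / 1000
  stats::setNames(counts * mini_vol, paste0("V", levels))
}

#' @rdname isodose_volumes
#' @param level single isodose level, %.
#' @export
isodose_volume <- function(dose, level, region,
                           scheme = supersampling_scheme(dose$grid$spacing,
                                                         dose$grid$spacing),
                           interp = "cubic") {
  unname(isodose_volumes(dose, level, region, scheme, interp))
}

#' Cumulative dose-volume histogram
#'
#' Histogram of mini-voxel doses inside a structure, accumulated from the
#' top: the curve value at dose d is the structure volume receiving at least
#' d (% of prescription). Mini-voxels subdivide the dose lattice per
#' `scheme`; membership uses the slab convention of [inside_structure()].
#'
#' @param struct an [rt_structure()].
#' @param dose a [dose_grid()].
#' @param bin_width histogram bin width, % of prescription (default 0.1).
#' @param scheme [supersampling_scheme()].
#' @param interp interpolant for [dose_at()].
#' @return object of class `dvh_curve`: `dose` (bin edges, %), `cum_cm3`,
#'   `cum_pct` (non-increasing; 100% at dose 0) and `total_cm3`.
#' @export
cumulative_dvh <- function(struct, dose, bin_width = 0.1,
                           scheme = supersampling_scheme(dose$grid$spacing,
                                                         dose$grid$spacing),
                           interp = "cubic") {
  region <- eval_region_structure(struct)
  doses <- unlist(map_mini_points(dose, region, scheme, function(pts, mv) {
    keep <- inside_structure(pts, struct)
    if (!any(keep)) return(numeric(0))
    suppressWarnings(as.numeric(dose_at(dose, pts[keep, , drop = FALSE], interp)))
  }))
  mini_vol <- prod(dose$grid$spacing / scheme$factor) / 1000
  if (!length(doses)) stop(sprintf("structure '%s' has zero sampled volume", struct$name))
  edges <- seq(0, max(doses) + bin_width, by = bin_width)
  idx <- findInterval(doses, edges, left.open = TRUE) + 1L
  counts <- tabulate(idx, nbins = length(edges))
  cum <- rev(cumsum(rev(counts))) * mini_vol
  structure(list(dose = edges, cum_cm3 = cum, cum_pct = 100 * cum / cum[1],
                 total_cm3 = cum[1], bin_width = bin_width),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve: volume %.4g cm^3, dose range [0, %.1f]%%, bin %.2g%%\n",
              x$total_cm3, max(x$dose), x$bin_width))
  invisible(x)
}

#' Minimum dose to the hottest 95% of the structure (D95)
#'
#' Largest dose level at which the cumulative relative volume is still at
#' least 95%, with linear interpolation between histogram bins.
#'
#' @param curve a `dvh_curve`.
#' @param q covered fraction, % (default 95).
#' @return dose in % of prescription.
#' @export
d95 <- function(curve, q = 95) {
  rel <- curve$cum_pct
  d <- curve$dose
  if (rel[length(rel)] >= q) return(d[length(d)])
  i <- max(which(rel >= q))           # last edge still covering q%
  # interpolate within (d[i], d[i+1]]
  r0 <- rel[i]; r1 <- rel[i + 1]
  if (r0 == r1) return(d[i])
  d[i] + (r0 - q) / (r0 - r1) * (d[i + 1] - d[i])
}

#' Relative volume at a dose level (V_dose, %)
#'
#' Percentage of the structure receiving at least `level`% of prescription
#' (inclusive threshold, so a uniform dose exactly at the level counts
#' fully).
#'
#' @param curve a `dvh_curve`.
#' @param level dose level, % of prescription.
#' @return volume in % of the structure volume.
#' @export
v_at_dose <- function(curve, level) {
  d <- curve$dose
  if (level <= d[1]) return(100)
  if (level > d[length(d)]) return(0)
  i <- findInterval(level, d)
  # curve value at an edge counts doses >= edge; interpolate within the bin
  r0 <- curve$cum_pct[i]
  r1 <- if (i < length(d)) curve$cum_pct[i + 1] else 0
  if (level == d[i]) return(r0)
  r0 + (level - d[i]) / (d[i + 1] - d[i]) * (r1 - r0)
}

#' Paddick conformity index
#'
#' `CI = TV_PIV^2 / (TV * PIV)` where TV is the target volume, PIV the
#' prescription isodose volume and TV_PIV the target volume covered by the
#' prescription dose. 1 means perfect conformity.
#'
#' @param tv,piv,tv_piv volumes, cm^3 (tv, piv > 0; tv_piv <= min(tv, piv)).
#' @return CI, dimensionless in (0, 1].
#' @export
conformity_index <- function(tv, piv, tv_piv) {
  stopifnot(tv > 0, piv > 0)
  if (tv_piv > min(tv, piv) * (1 + 1e-9))
    stop("inconsistent volumes: TV_PIV exceeds min(TV, PIV)")
  tv_piv^2 / (tv * piv)
}

#' Gradient index
#'
#' `GI = V50%Rx / V100%Rx`, the ratio of the half-prescription isodose
#' volume to the prescription isodose volume; smaller means steeper falloff.
#'
#' @param v50,v100 volumes, cm^3 (v100 > 0).
#' @return GI, dimensionless (>= 1 for nested isodoses).
#' @export
gradient_index <- function(v50, v100) {
  if (v100 <= 0) stop("V100 must be positive")
  v50 / v100
}

#' SRS plan-quality indices for one target
#'
#' Computes, in one mini-voxel pass over the target's evaluation region:
#' the V_dose volumes (cm^3) at the requested levels, the target DVH and
#' D95 / V30Gy (the percentage of the target at or above prescription), and
#' the Paddick CI and GI. PIV and TV_PIV are restricted to the evaluation
#' region, honouring the shell-isolation rule; TV is the supersampled
#' structure volume on the CT grid (parabolic end-cap).
#'
#' @param target an [rt_structure()].
#' @param dose a [dose_grid()].
#' @param region an `eval_region` containing the target.
#' @param ct_grid CT [voxel_grid()] used for the structure volume.
#' @param levels V_dose levels, % of prescription.
#' @param bin_width DVH bin width, %.
#' @param scheme [supersampling_scheme()] for the dose mini-voxels.
#' @param interp interpolant for [dose_at()].
#' @return list with `vdose` (named cm^3), `TV`, `PIV`, `TV_PIV` (cm^3),
#'   `CI`, `GI`, `D95`, `V30Gy`, and the `dvh` curve.
#' @export
plan_indices <- function(target, dose, region, ct_grid,
                         levels = c(110, 100, 98, 95, 80, 50),
                         bin_width = 0.1,
                         scheme = supersampling_scheme(dose$grid$spacing,
                                                       dose$grid$spacing),
                         interp = "cubic") {
  levels <- sort(unique(c(levels, 100, 50)), decreasing = TRUE)
  counts <- numeric(length(levels))
  n_cov <- 0L
  target_doses <- list()
  chunks <- map_mini_points(dose, region, scheme, function(pts, mv) {
    in_reg <- region_contains(region, pts)
    if (!any(in_reg)) return(list(cnt = numeric(length(levels)), cov = 0L, td = numeric(0)))
    pts <- pts[in_reg, , drop = FALSE]
    d <- suppressWarnings(as.numeric(dose_at(dose, pts, interp)))
    in_tgt <- inside_structure(pts, target)
    list(cnt = vapply(levels, function(L) sum(d >= L), 0),
         cov = sum(in_tgt & d >= 100),
         td = d[in_tgt])
  })
  mini_vol <- prod(dose$grid$spacing / scheme$factor) / 1000
  for (ch in chunks) {
    counts <- counts + ch$cnt
    n_cov <- n_cov + ch$cov
    if (length(ch$td)) target_doses[[length(target_doses) + 1L]] <- ch$td
  }
  vdose <- stats::setNames(counts * mini_vol, paste0("V", levels))
  td <- unlist(target_doses)
  if (!length(td)) stop(sprintf("target '%s' has zero sampled volume", target$name))
  edges <- seq(0, max(td) + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(td, edges, left.open = TRUE) + 1L,
                  nbins = length(edges))
  cum <- rev(cumsum(rev(cnt))) * mini_vol
  dvh <- structure(list(dose = edges, cum_cm3 = cum,
                        cum_pct = 100 * cum / cum[1], total_cm3 = cum[1],
                        bin_width = bin_width), class = "dvh_curve")
  tv <- structure_volume(target, ct_grid)$volume
  piv <- unname(vdose["V100"])
  tv_piv <- min(n_cov * mini_vol, tv, piv)
  list(vdose = vdose, TV = tv, PIV = piv, TV_PIV = tv_piv,
       CI = conformity_index(tv, piv, tv_piv),
       GI = gradient_index(unname(vdose["V50"]), piv),
       D95 = d95(dvh), V30Gy = v_at_dose(dvh, 100), dvh = dvh)
}
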