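#' Point-in-polygon containment
#'
#' Even-odd (crossing-number) test of 2-D points against one closed polygon
#' ring. Points on the boundary count as inside (within `eps` mm of an
#' edge); this tie rule is used consistently by every rasterisation in the
#' package.
#'
#' @param x,y point coordinates, mm (vectors of equal length), or `x` may be
#'   an n x 2 matrix with `y` missing.
#' @param poly a [planar_contour()] or an n x 2 vertex matrix.
#' @param eps boundary tolerance, mm.
#' @return logical vector.
#' @examples
#' sq <- planar_contour(0, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' point_in_polygon(c(0.5, 2, 1.0), c(0.5, 0.5, 0.5), sq)  # TRUE FALSE TRUE
#' @export
point_in_polygon <- function(x, y = NULL, poly, eps = 1e-9) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  verts <- if (inherits(poly, "planar_contour")) poly$vertices else as.matrix(poly)
  if (nrow(unique(round(verts, 9))) < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices")
  cpp_points_in_polygon(as.numeric(x), as.numeric(y), verts, eps)
}

#' Hierarchical supersampling configuration
#'
#' Voxels are subdivided in two stages mirroring common TPS practice: voxels
#' larger than `sub_voxel_mm3` (1 mm^3) are first split into equal sub-voxels
#' no larger than that, and sub-voxels are further split into "mini-voxels"
#' whose volume is at most `1/ratio` (default 1/27) of the dose-voxel volume.
#' The result is a single per-axis subdivision factor applied to voxel
#' edges.
#'
#' @param voxel_spacing numeric(3), mm, the voxels being subdivided.
#' @param dose_spacing numeric(3), mm, the governing dose grid (defaults to
#'   1 mm isotropic).
#' @param factor override: explicit per-axis factor(s); bypasses the rule.
#' @param sub_voxel_mm3 first-stage sub-voxel volume bound, mm^3.
#' @param ratio mini-voxel : dose-voxel volume ratio bound.
#' @return object of class `supersampling` with integer `factor` (length 3).
#' @export
supersampling_scheme <- function(voxel_spacing, dose_spacing = c(1, 1, 1),
                                 factor = NULL, sub_voxel_mm3 = 1, ratio = 27) {
  voxel_spacing <- rep_len(as.numeric(voxel_spacing), 3L)
  dose_spacing <- rep_len(as.numeric(dose_spacing), 3L)
  if (is.null(factor)) {
    vol <- prod(voxel_spacing)
    f1 <- 1L
    while (vol / f1^3 > sub_voxel_mm3 + 1e-12) f1 <- f1 + 1L
    sub_vol <- vol / f1^3
    dose_vol <- prod(dose_spacing)
    f2 <- 1L
    while (sub_vol / f2^3 > dose_vol / ratio + 1e-12) f2 <- f2 + 1L
    factor <- f1 * f2
  }
  factor <- rep_len(as.integer(factor), 3L)
  stopifnot(all(factor >= 1L))
  structure(list(factor = factor, voxel_spacing = voxel_spacing,
                 dose_spacing = dose_spacing), class = "supersampling")
}

#' @export
print.supersampling <- function(x, ...) {
  cat(sprintf("supersampling: %d x %d x %d sub-points per voxel\n",
              x$factor[1], x$factor[2], x$factor[3]))
  invisible(x)
}

# Sub-sample offsets (mm) for one axis: f points centred in the voxel.
sub_offsets <- function(spacing, f) ((seq_len(f) - (f + 1) / 2) / f) * spacing

# Index of the governing contour slab for z positions. Contour at zc governs
# [zc - st/2, zc + st/2). Returns an index into `slice_zs` or NA.
slab_index <- function(z, slice_zs, st) {
  idx <- findInterval(z, slice_zs - st / 2 + 1e-12)
  idx[idx < 1L] <- NA_integer_
  off <- z - slice_zs[pmax(idx, 1L)]
  idx[!is.na(idx) & off >= st / 2 - 1e-12] <- NA_integer_
  idx
}

# Fractional in-plane occupancy of the rings at one slice, on the pixel
# lattice (xs, ys) with per-pixel fx x fy sub-points. Returns a matrix
# length(xs) x length(ys) of fractions in [0, 1].
plane_occupancy <- function(rings, xs, ys, dx, dy, fx, fy, eps = 1e-9) {
  offx <- sub_offsets(dx, fx); offy <- sub_offsets(dy, fy)
  sx <- as.vector(outer(xs, offx, `+`)); ox <- order(sx); sx <- sx[ox]
  sy <- as.vector(outer(ys, offy, `+`)); oy <- order(sy); sy <- sy[oy]
  px <- rep(sx, times = length(sy))
  py <- rep(sy, each = length(sx))
  parity <- integer(length(px))
  for (rg in rings)
    parity <- cpp_accumulate_ring(parity, px, py, rg$vertices, eps)
  m <- matrix(parity, nrow = length(sx))
  # undo ordering, then average the f x f blocks back onto the pixel lattice
  m <- m[order(ox), order(oy), drop = FALSE]
  nx <- length(xs); ny <- length(ys)
  blk <- matrix(0, nx, ny)
  for (a in seq_len(fx)) for (b in seq_len(fy))
    blk <- blk + m[seq(a, by = fx, length.out = nx),
                   seq(b, by = fy, length.out = ny), drop = FALSE]
  blk / (fx * fy)
}

#' Rasterise a structure onto a voxel lattice
#'
#' Converts a planar-contour structure into per-voxel occupancy fractions on
#' (a crop of) `grid`. Each voxel is subdivided per `scheme`; a sub-point at
#' height z is tested against the contour(s) of the slab containing z
#' (contour at zc governs `[zc - st/2, zc + st/2)`; the first and last
#' contours therefore extend half a slice beyond their position, the
#' half-slab end-capping convention). In-plane containment uses
#' [point_in_polygon()] with the even-odd rule across rings, so annular
#' slices behave correctly. The fraction of a voxel is the proportion of its
#' sub-points contained, deterministic given the scheme.
#'
#' @param struct an [rt_structure()].
#' @param grid the [voxel_grid()] to rasterise onto (normally the CT grid).
#' @param scheme a [supersampling_scheme()]; default derives from the grid
#'   spacing against a 1-mm dose grid.
#' @return object of class `occupancy`: the cropped sub-grid (`grid`), the
#'   3-D `fraction` array, and per-slice bookkeeping used by
#'   [structure_volume()].
#' @export
rasterize_structure <- function(struct, grid,
                                scheme = supersampling_scheme(grid$spacing)) {
  stopifnot(inherits(struct, "rt_structure"), inherits(grid, "voxel_grid"))
  zs <- contour_z(struct)
  if (min(zs) < grid_zmin(grid) - grid$spacing[3] / 2 - 1e-9 ||
      max(zs) > grid_zmax(grid) + grid$spacing[3] / 2 + 1e-9)
    stop(sprintf("contours of '%s' at z in [%g, %g] lie outside the grid z extent",
                 struct$name, min(zs), max(zs)))
  bb <- structure_bbox(struct)
  sub <- crop_grid(grid, bb$lo, bb$hi, pad = grid$spacing)
  ax <- grid_axes(sub)
  f <- scheme$factor
  frac <- array(0, sub$dims)
  uz <- unique(zs)
  st <- struct$st
  # per-slice ring groups
  groups <- lapply(uz, function(z) struct$contours[abs(zs - z) < 1e-9])
  areas <- numeric(length(uz))
  pix <- sub$spacing[1] * sub$spacing[2]
  # z sub-points of the lattice, assigned to slabs
  offz <- sub_offsets(sub$spacing[3], f[3])
  zsub <- as.vector(outer(ax$z, offz, `+`))  # length nz * fz
  slab <- slab_index(zsub, uz, st)
  for (g in seq_along(uz)) {
    rings <- groups[[g]]
    occ2d <- plane_occupancy(rings, ax$x, ax$y, sub$spacing[1], sub$spacing[2],
                             f[1], f[2])
    areas[g] <- sum(occ2d) * pix
    hit <- which(slab == g)
    if (!length(hit)) next
    kz <- ((hit - 1L) %% sub$dims[3]) + 1L
    w <- table(kz)
    for (nm in names(w))
      frac[, , as.integer(nm)] <- frac[, , as.integer(nm)] +
        occ2d * (as.integer(w[[nm]]) / f[3])
  }
  structure(list(grid = sub, fraction = frac, scheme = scheme,
                 slice_z = uz, slice_area = areas, st = st,
                 name = struct$name),
            class = "occupancy")
}

#' @export
print.occupancy <- function(x, ...) {
  cat(sprintf("occupancy of '%s': %d x %d x %d voxels, summed volume %.4g cm^3\n",
              x$name, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              sum(x$fraction) * voxel_volume(x$grid) / 1000))
  invisible(x)
}

# Integrate a cross-section area profile A(z) with a locally-quadratic rule
# and quadratic end-cap extrapolation to the zero-crossing of A (clipped to
# one slice beyond the end contour). Exact for quadratic profiles, i.e. for
# spheres and ellipsoids. Falls back to half-slab capping for < 3 slices.
integrate_area_profile <- function(z, A, st) {
  keep <- A > 0
  z <- z[keep]; A <- A[keep]
  n <- length(z)
  if (n == 0L) return(0)
  if (n == 1L) return(A * st)
  if (n == 2L) return(sum(A) * st)          # trapezoid body + half-slab caps
  quad_coef <- function(idx) {
    zc <- z[idx] - z[idx[2]]                # centre for conditioning
    co <- solve(cbind(1, zc, zc^2), A[idx])
    c(co[1] - co[2] * z[idx[2]] + co[3] * z[idx[2]]^2,
      co[2] - 2 * co[3] * z[idx[2]], co[3])
  }
  quad_int <- function(co, a, b)
    co[1] * (b - a) + co[2] * (b^2 - a^2) / 2 + co[3] * (b^3 - a^3) / 3
  body <- 0
  for (k in seq_len(n - 1L)) {
    idx <- if (k == 1L) 1:3 else if (k == n - 1L) (n - 2L):n else (k - 1L):(k + 1L)
    body <- body + quad_int(quad_coef(idx), z[k], z[k + 1L])
  }
  cap <- 0
  for (end in c(1L, n)) {
    idx <- if (end == 1L) 1:3 else (n - 2L):n
    co <- quad_coef(idx)
    dir <- if (end == 1L) -1 else 1
    h <- st
    if (abs(co[3]) > 1e-12) {
      disc <- co[2]^2 - 4 * co[3] * co[1]
      if (disc >= 0) {
        roots <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
        cand <- (roots - z[end]) * dir
        cand <- cand[cand > 0]
        if (length(cand)) h <- min(cand, st)
      }
    }
    tt <- seq(z[end], z[end] + dir * h, length.out = 65L)
    Av <- pmax(co[1] + co[2] * tt + co[3] * tt^2, 0)
    cap <- cap + sum((Av[-1] + Av[-length(Av)]) / 2) * abs(tt[2] - tt[1])
  }
  body + cap
}

#' Structure volume from supersampled rasterisation
#'
#' Two end-capping conventions are offered. `"parabolic"` (default, the
#' reporting convention) integrates the supersampled per-slice cross-section
#' areas over z with a locally-quadratic rule, extrapolating the end caps
#' quadratically to the area zero-crossing (exact for spheres/ellipsoids,
#' and accurate for any smoothly capped lesion). `"half-slab"` sums the
#' occupancy fractions times the voxel volume, the slab convention used by
#' the DVH path: each contour governs a full slab, ends extended half a
#' slice.
#'
#' @param struct an [rt_structure()] (or a precomputed `occupancy`).
#' @param grid CT [voxel_grid()] (ignored when `struct` is an occupancy).
#' @param scheme a [supersampling_scheme()].
#' @param end_cap `"parabolic"` or `"half-slab"`.
#' @return object of class `volume_result` with `volume` (cm^3), `method`,
#'   `scheme` and `se` (NA except for Monte Carlo results).
#' @export
structure_volume <- function(struct, grid,
                             scheme = supersampling_scheme(grid$spacing),
                             end_cap = c("parabolic", "half-slab")) {
  end_cap <- match.arg(end_cap)
  occ <- if (inherits(struct, "occupancy")) struct
         else rasterize_structure(struct, grid, scheme)
  vol_mm3 <- if (end_cap == "parabolic")
    integrate_area_profile(occ$slice_z, occ$slice_area, occ$st)
  else
    sum(occ$fraction) * voxel_volume(occ$grid)
  volume_result(unname(vol_mm3) / 1000, method = "supersampled",
                scheme = occ$scheme, end_cap = end_cap)
}

volume_result <- function(volume_cm3, method, scheme = NULL, end_cap = NULL,
                          se = NA_real_) {
  stopifnot(volume_cm3 >= 0)
  structure(list(volume = volume_cm3, method = method, scheme = scheme,
                 end_cap = end_cap, se = se), class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("volume: %.6g cm^3 (%s%s)%s\n", x$volume, x$method,
              if (!is.null(x$end_cap)) paste0(", ", x$end_cap, " end-cap") else "",
              if (is.finite(x$se)) sprintf(" SE %.3g cm^3", x$se) else ""))
  invisible(x)
}

#' Regenerate or resample a structure at a new slice thickness
#'
#' Analytic structures are re-contoured exactly at the new slice positions
#' from their shape equation. Imported polygon stacks are resampled: each
#' new slice takes the contour set whose original z is nearest (ties broken
#' toward the inferior z), provided one lies within one new slice thickness.
#' The new slice ladder shares `origin` (common Image-Position-Patient
#' semantics): positions are `origin[3] + k * new_st`.
#'
#' @param struct an [rt_structure()].
#' @param new_st new slice thickness, mm.
#' @param origin numeric(3) (only the z component is used), the common
#'   lattice origin.
#' @return an [rt_structure()]; warns and returns `NULL` if no contour falls
#'   within one `new_st` of any new slice.
#' @export
reslice_structure <- function(struct, new_st, origin) {
  stopifnot(new_st > 0)
  z0 <- origin[3]
  if (!is.null(struct$analytic)) {
    a <- struct$analytic
    czr <- a$center[3] + c(-1, 1) * a$radius
    ks <- seq(floor((czr[1] - z0) / new_st) - 1L, ceiling((czr[2] - z0) / new_st) + 1L)
    slice_z <- z0 + ks * new_st
    contours <- contours_from_analytic(a, slice_z)
    if (!length(contours)) {
      warning(sprintf("structure '%s' becomes empty at ST %g mm", struct$name, new_st))
      return(NULL)
    }
    return(rt_structure(struct$name, contours, st = new_st, analytic = a))
  }
  zs <- contour_z(struct)
  uz <- unique(zs)
  ks <- seq(floor((min(uz) - z0) / new_st), ceiling((max(uz) - z0) / new_st))
  out <- list()
  for (k in ks) {
    znew <- z0 + k * new_st
    d <- abs(uz - znew)
    if (min(d) > new_st) next
    pick <- uz[which(d == min(d))]
    pick <- min(pick)                       # tie -> inferior z
    for (cc in struct$contours[abs(zs - pick) < 1e-9])
      out[[length(out) + 1L]] <- planar_contour(znew, cc$vertices)
  }
  if (!length(out)) {
    warning(sprintf("structure '%s' becomes empty at ST %g mm", struct$name, new_st))
    return(NULL)
  }
  rt_structure(struct$name, out, st = new_st, analytic = NULL)
}

#' Monte Carlo volume oracle
#'
#' Estimates the volume of `{p : inside(p)}` within an axis-aligned bounding
#' box by uniform rejection sampling. Used as an independent reference for
#' the deterministic rasterised volumes.
#'
#' @param inside vectorised predicate taking an n x 3 matrix of points (mm)
#'   and returning a logical vector.
#' @param bbox list with numeric(3) `lo` and `hi`, mm.
#' @param n number of draws (>= 1e4).
#' @param seed RNG seed.
#' @return a `volume_result` (cm^3) with standard error `se`.
#' @export
mc_volume_oracle <- function(inside, bbox, n = 1e6, seed = 1) {
  stopifnot(n >= 1e4)
  lo <- as.numeric(bbox$lo); hi <- as.numeric(bbox$hi)
  vbox <- prod(hi - lo)
  if (vbox <= 0) stop("zero-measure bounding box")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
  hits <- mean(inside(p))
  se <- vbox * sqrt(hits * (1 - hits) / n)
  volume_result(vbox * hits / 1000, method = "monte-carlo",
                se = max(se, vbox / n) / 1000)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
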