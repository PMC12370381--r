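#' Regular voxel lattice geometry
#'
#' A `voxel_grid` describes the geometry of a regular 3-D lattice shared by
#' CT volumes and dose matrices: the position of the first voxel centre
#' (`origin`, mm, patient coordinates), the voxel pitch per axis (`spacing`,
#' mm; the z spacing is the CT slice thickness ST or the dose-grid
#' resolution DG), and the number of voxels per axis (`dims`). Axis order is
#' (x, y, z). Slice positions are `origin[3] + k * spacing[3]` for
#' `k = 0 .. dims[3] - 1`. Two grids share a common origin iff their origins
#' are identical.
#'
#' @param origin numeric(3), mm; centre of the first voxel.
#' @param spacing numeric(3), mm; strictly positive.
#' @param dims integer(3), strictly positive voxel counts.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(0, 0, 0), c(0.6, 0.6, 1), c(50, 50, 30))
#' voxel_volume(g)  # mm^3
#' @export
voxel_grid <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  if (any(spacing <= 0)) stop("grid spacing must be strictly positive")
  if (any(dims < 1L)) stop("grid dims must be positive integers")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel centre coordinates along each axis
#'
#' @param grid a [voxel_grid()].
#' @return list with numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  list(x = grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing[3])
}

#' Volume of one voxel in mm^3
#' @param grid a [voxel_grid()].
#' @return numeric scalar, mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Crop a grid to a bounding box, staying on the parent lattice
#'
#' Returns the sub-grid of voxels whose centres lie within `[lo - pad, hi + pad]`
#' per axis. Voxel centres of the result coincide with parent voxel centres,
#' so values sampled on the sub-grid are directly comparable with the parent.
#'
#' @param grid a [voxel_grid()].
#' @param lo,hi numeric(3) corners of the box, mm.
#' @param pad numeric scalar or numeric(3), extra margin in mm.
#' @return a [voxel_grid()].
#' @export
crop_grid <- function(grid, lo, hi, pad = 0) {
  stopifnot(inherits(grid, "voxel_grid"))
  pad <- rep_len(as.numeric(pad), 3L)
  i0 <- pmax(ceiling((lo - pad - grid$origin) / grid$spacing - 1e-9), 0)
  i1 <- pmin(floor((hi + pad - grid$origin) / grid$spacing + 1e-9), grid$dims - 1)
  if (any(i1 < i0)) stop("crop box does not intersect the grid")
  voxel_grid(grid$origin + i0 * grid$spacing, grid$spacing, i1 - i0 + 1)
}

grid_zmin <- function(grid) grid$origin[3]
grid_zmax <- function(grid) grid$origin[3] + (grid$dims[3] - 1) * grid$spacing[3]
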