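#' Planar contour
#'
#' One closed planar polygon at a fixed slice position, the unit from which
#' RT structures are built. Vertices are stored as an n x 2 matrix of (x, y)
#' in mm; the ring is implicitly closed and normalised to counter-clockwise
#' orientation. A valid contour has at least 3 distinct vertices.
#'
#' @param z slice position, mm.
#' @param vertices n x 2 numeric matrix of (x, y) mm.
#' @return object of class `planar_contour`.
#' @export
planar_contour <- function(z, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("contour vertices must be an n x 2 matrix")
  if (nrow(unique(round(vertices, 9))) < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices")
  if (signed_area(vertices) < 0) vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  structure(list(z = as.numeric(z), vertices = unname(vertices)),
            class = "planar_contour")
}

signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  sum(x * c(y[-1], y[1]) - y * c(x[-1], x[1])) / 2
}

#' An RT structure: a stack of planar contours
#'
#' Contours are kept sorted by slice position; several rings may share one
#' slice (multi-ring slices combine by the even-odd rule, so annular
#' structures are representable). `st` is the nominal slice spacing (mm) used
#' by the slab convention; when omitted it is inferred from the contour z
#' ladder. `analytic` optionally carries the closed-form shape descriptor
#' (see [sphere_structure()]) so the structure can be regenerated at a new
#' slice thickness.
#'
#' @param name structure name.
#' @param contours list of [planar_contour()].
#' @param st slice thickness, mm (optional).
#' @param analytic optional analytic shape descriptor.
#' @return object of class `rt_structure`.
#' @export
rt_structure <- function(name, contours, st = NULL, analytic = NULL) {
  if (!length(contours)) stop(sprintf("structure '%s' has no contours", name))
  stopifnot(all(vapply(contours, inherits, TRUE, "planar_contour")))
  zs <- vapply(contours, `[[`, 0, "z")
  contours <- contours[order(zs)]
  zs <- sort(zs)
  if (is.null(st)) {
    uz <- unique(zs)
    st <- if (length(uz) > 1L) min(diff(uz)) else 1
  }
  structure(list(name = name, contours = contours, st = as.numeric(st),
                 analytic = analytic),
            class = "rt_structure")
}

contour_z <- function(struct) vapply(struct$contours, `[[`, 0, "z")

structure_zrange <- function(struct) {
  z <- contour_z(struct)
  c(min(z) - struct$st / 2, max(z) + struct$st / 2)
}

structure_bbox <- function(struct) {
  xy <- do.call(rbind, lapply(struct$contours, `[[`, "vertices"))
  zr <- structure_zrange(struct)
  list(lo = c(min(xy[, 1]), min(xy[, 2]), zr[1]),
       hi = c(max(xy[, 1]), max(xy[, 2]), zr[2]))
}

#' @export
print.rt_structure <- function(x, ...) {
  z <- contour_z(x)
  cat(sprintf("rt_structure '%s': %d contour(s) on %d slice(s), z in [%g, %g] mm, ST %g mm%s\n",
              x$name, length(x$contours), length(unique(z)), min(z), max(z), x$st,
              if (!is.null(x$analytic)) sprintf(" [analytic: %s]", x$analytic$type) else ""))
  invisible(x)
}

#' Named collection of structures sharing a frame of reference
#'
#' @param structures list of [rt_structure()] (named by structure).
#' @param frame_of_reference identifier string.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(structures = list(), frame_of_reference = "FOR-1") {
  if (length(structures)) {
    stopifnot(all(vapply(structures, inherits, TRUE, "rt_structure")))
    names(structures) <- vapply(structures, `[[`, "", "name")
  }
  structure(list(structures = structures,
                 frame_of_reference = frame_of_reference),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("structure_set (%s): %d structure(s)\n",
              x$frame_of_reference, length(x$structures)))
  invisible(x)
}

#' Analytic sphere contoured on a slice ladder
#'
#' Generates the planar contours a clinician would draw for a sphere on axial
#' slices: on each slice position `z` intersecting the sphere, a regular
#' polygon of `n_vertices` vertices inscribed in the circle of radius
#' `sqrt(R^2 - (z - cz)^2)` evaluated at the slice position (no slab
#' averaging). Slices grazing the sphere with a vanishing circle are skipped.
#'
#' @param center numeric(3), mm.
#' @param diameter sphere diameter, mm.
#' @param slice_z numeric vector of slice positions, mm (usually the CT
#'   slice ladder of a [voxel_grid()]).
#' @param st slice thickness, mm.
#' @param name structure name.
#' @param n_vertices vertices per circle (default 64).
#' @param phase azimuthal offset of the first vertex, radians.
#' @return an [rt_structure()] carrying an analytic descriptor, so it can be
#'   resliced exactly with [reslice_structure()].
#' @export
sphere_structure <- function(center, diameter, slice_z, st, name = "sphere",
                             n_vertices = 64L, phase = 0) {
  R <- diameter / 2
  stopifnot(R > 0, n_vertices >= 3L)
  analytic <- list(type = "sphere", center = as.numeric(center), radius = R,
                   n_vertices = as.integer(n_vertices), phase = phase)
  contours <- contours_from_analytic(analytic, slice_z)
  if (!length(contours))
    stop(sprintf("sphere '%s' intersects no slice position", name))
  rt_structure(name, contours, st = st, analytic = analytic)
}

#' Irregular lesion: sphere with azimuthal radial perturbation
#'
#' Clinical-like target shapes are spheres whose in-plane radius is modulated
#' by low-order azimuthal harmonics, `rho(phi, z) = rho_sphere(z) * m(phi)`
#' with `m(phi) = (1 + sum_k a_k cos(k phi + psi_k)) / max(...)`, normalised
#' so the maximum axial diameter equals `diameter` (diameter labels mean
#' maximum axial diameter). `max_radius` of the descriptor bounds the shape.
#'
#' @param center numeric(3) mm; @param diameter maximum axial diameter, mm.
#' @param slice_z slice ladder positions, mm; @param st slice thickness, mm.
#' @param harmonics named list with integer vector `k`, amplitudes `a` and
#'   phases `psi` (radians).
#' @param name structure name; @param n_vertices vertices per ring.
#' @return an [rt_structure()] with analytic descriptor of type "blob".
#' @export
blob_structure <- function(center, diameter, slice_z, st,
                           harmonics = list(k = integer(), a = numeric(), psi = numeric()),
                           name = "lesion", n_vertices = 64L) {
  R <- diameter / 2
  stopifnot(R > 0)
  analytic <- list(type = "blob", center = as.numeric(center), radius = R,
                   harmonics = harmonics, n_vertices = as.integer(n_vertices),
                   phase = 0)
  contours <- contours_from_analytic(analytic, slice_z)
  if (!length(contours))
    stop(sprintf("lesion '%s' intersects no slice position", name))
  rt_structure(name, contours, st = st, analytic = analytic)
}

blob_modulation <- function(phi, harmonics) {
  m <- rep(1, length(phi))
  if (length(harmonics$k))
    for (i in seq_along(harmonics$k))
      m <- m + harmonics$a[i] * cos(harmonics$k[i] * phi + harmonics$psi[i])
  m
}

blob_max_modulation <- function(harmonics) {
  phi <- seq(0, 2 * pi, length.out = 721L)
  max(blob_modulation(phi, harmonics))
}

contours_from_analytic <- function(analytic, slice_z) {
  cz <- analytic$center[3]
  R <- analytic$radius
  nv <- analytic$n_vertices
  phi <- analytic$phase + 2 * pi * (seq_len(nv) - 1) / nv
  out <- list()
  for (z in slice_z) {
    r2 <- R^2 - (z - cz)^2
    if (r2 <= 0) next
    rho <- sqrt(r2)
    if (identical(analytic$type, "blob")) {
      mod <- blob_modulation(phi, analytic$harmonics) / blob_max_modulation(analytic$harmonics)
      rho <- rho * mod
    }
    out[[length(out) + 1L]] <- planar_contour(
      z, cbind(analytic$center[1] + rho * cos(phi),
               analytic$center[2] + rho * sin(phi)))
  }
  out
}

#' Largest in-plane radius of an analytic shape, mm
#' @param struct an [rt_structure()] with an analytic descriptor.
#' @keywords internal
analytic_max_radius <- function(struct) {
  a <- struct$analytic
  if (is.null(a)) stop("structure has no analytic descriptor")
  a$radius
}
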