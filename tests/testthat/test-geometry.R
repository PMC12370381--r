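test_that("point_in_polygon handles interior, exterior and boundary points", {
  sq <- unit_square()
  cases <- list(
    list(p = c(0.5, 0.5), expect = TRUE),   # interior
    list(p = c(2.0, 0.5), expect = FALSE),  # exterior
    list(p = c(1.0, 0.5), expect = TRUE),   # on an edge: boundary is inside
    list(p = c(0.0, 0.0), expect = TRUE),   # vertex
    list(p = c(-1e-6, 0.5), expect = FALSE))
  for (cs in cases)
    expect_identical(point_in_polygon(cs$p[1], cs$p[2], sq), cs$expect,
                     label = paste("point", paste(cs$p, collapse = ",")))
  # vectorised call agrees with scalar calls
  px <- runif(50, -0.5, 1.5); py <- runif(50, -0.5, 1.5)
  expect_identical(point_in_polygon(px, py, sq),
                   vapply(seq_along(px), function(i)
                     point_in_polygon(px[i], py[i], sq), TRUE))
  expect_error(point_in_polygon(0, 0, rbind(c(0, 0), c(1, 1), c(0, 0))),
               "degenerate")
})

test_that("orientation is normalised and even-odd rule makes annuli", {
  cw <- planar_contour(0, rbind(c(0, 1), c(1, 1), c(1, 0), c(0, 0)))
  expect_gt(srsdvh:::signed_area(cw$vertices), 0)  # normalised to CCW
  ring <- function(r, n = 64) {
    th <- 2 * pi * (0:(n - 1)) / n
    planar_contour(0, cbind(r * cos(th), r * sin(th)))
  }
  annulus <- rt_structure("annulus", list(ring(2), ring(1)), st = 1)
  p <- rbind(c(1.5, 0, 0),   # inside outer, outside inner -> in
             c(0.2, 0, 0),   # inside both rings -> out (even parity)
             c(2.5, 0, 0))   # outside both -> out
  expect_identical(inside_structure(p, annulus), c(TRUE, FALSE, FALSE))
})

test_that("single-slice square rasterises to the slab-forced volume", {
  s <- square_structure()
  g <- voxel_grid(c(-2, -2, -3), c(0.6, 0.6, 1), c(25, 25, 7))
  v <- structure_volume(s, g, end_cap = "half-slab")
  # 10 x 10 mm x 1 mm slab = 0.100 cm^3 forced by the convention
  expect_equal(v$volume, 0.100, tolerance = 1e-3)
  # occupancy conservation: volume equals sum(fraction) * voxel volume
  occ <- rasterize_structure(s, g)
  expect_equal(v$volume, sum(occ$fraction) * voxel_volume(occ$grid) / 1000,
               tolerance = 1e-12)
})

test_that("contours outside the grid z extent raise a named error", {
  s <- square_structure(z = 40)
  g <- ct_grid_mm()
  expect_error(rasterize_structure(s, g), "square")
})

test_that("supersampled sphere volumes agree with the Monte Carlo oracle", {
  g <- ct_grid_mm()
  for (D in c(7, 10)) {
    cen <- c(14.3, 15.2, 15.6)
    s <- sphere_fixture(cen, D, g)
    v <- structure_volume(s, g)$volume
    mc <- mc_volume_oracle(sphere_inside_fn(cen, D),
                           list(lo = cen - D / 2 - 1, hi = cen + D / 2 + 1),
                           n = 1e6, seed = 1)
    expect_lt(abs(v - mc$volume), 3 * mc$se,
              label = sprintf("D = %g supersampled vs MC", D))
  }
})

test_that("mc_volume_oracle matches closed forms and symmetry", {
  box <- list(lo = c(0, 0, 0), hi = c(1, 1, 1))
  v <- mc_volume_oracle(function(p) rep(TRUE, nrow(p)), box, n = 1e4, seed = 2)
  expect_equal(v$volume, 1e-3)   # the whole 1 mm^3 cube, in cm^3
  half <- mc_volume_oracle(function(p) p[, 1] <= 0.5, box, n = 1e5, seed = 3)
  expect_lt(abs(half$volume - 5e-4), 3 * half$se + 1e-12)
  sph <- mc_volume_oracle(sphere_inside_fn(c(7, 7, 7), 10),
                          list(lo = c(1, 1, 1), hi = c(13, 13, 13)),
                          n = 1e6, seed = 1)
  expect_lt(abs(sph$volume * 1000 - 523.5988), 3 * sph$se * 1000)
  expect_error(mc_volume_oracle(function(p) TRUE,
                                list(lo = c(0, 0, 0), hi = c(0, 1, 1)), n = 1e4),
               "zero-measure")
})

test_that("doubling the supersampling factor moves volumes by < 0.5%", {
  g <- ct_grid_mm()
  for (D in c(7, 15)) {
    s <- sphere_fixture(c(14.3, 15.2, 15.6), D, g)
    v1 <- structure_volume(s, g, supersampling_scheme(g$spacing, factor = 3))$volume
    v2 <- structure_volume(s, g, supersampling_scheme(g$spacing, factor = 6))$volume
    expect_lt(abs(v2 / v1 - 1) * 100, 0.5)
  }
})

test_that("volume is invariant under a common translation of structure and grid", {
  g <- ct_grid_mm()
  shift <- c(3.6, 1.2, 2)   # a whole number of voxels per axis
  g2 <- voxel_grid(g$origin + shift, g$spacing, g$dims)
  s1 <- sphere_fixture(c(14.3, 15.2, 15.6), 10, g)
  s2 <- sphere_fixture(c(14.3, 15.2, 15.6) + shift, 10, g2)
  expect_equal(structure_volume(s1, g)$volume,
               structure_volume(s2, g2)$volume, tolerance = 1e-12)
})

test_that("adding a contour never reduces the rasterised volume", {
  g <- ct_grid_mm()
  full <- sphere_fixture(c(14.3, 15.2, 15.6), 10, g)
  zs <- contour_z(full)
  vols <- vapply(seq_along(full$contours), function(k) {
    part <- rt_structure("part", full$contours[seq_len(k)], st = full$st)
    structure_volume(part, g, end_cap = "half-slab")$volume
  }, 0)
  expect_true(all(diff(vols) >= -1e-12))
})

test_that("analytic reslice preserves identity and accuracy", {
  g <- ct_grid_mm(extent = c(30, 30, 30))
  s <- sphere_fixture(c(14.3, 15.2, 15.6), 20, g)
  same <- reslice_structure(s, g$spacing[3], g$origin)
  expect_equal(contour_z(same), contour_z(s))
  coarse <- reslice_structure(s, 2, g$origin)
  g2 <- voxel_grid(g$origin, c(0.6, 0.6, 2), c(g$dims[1:2], 16))
  v <- structure_volume(coarse, g2)$volume
  expect_lt(abs(v / sphere_volume(20) - 1) * 100, 5)
  # a 3-mm sphere centred between 2-mm slices still gets a nonzero volume
  tiny <- sphere_fixture(c(14.3, 15.2, 15.0), 3, g)
  tiny2 <- reslice_structure(tiny, 2, g$origin)
  g3 <- voxel_grid(g$origin, c(0.6, 0.6, 2), c(g$dims[1:2], 16))
  expect_gt(structure_volume(tiny2, g3)$volume, 0)
})

test_that("polygon reslice picks the nearest contour, ties inferior", {
  sq1 <- planar_contour(10, rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  sq2 <- planar_contour(11, rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)))
  s <- rt_structure("steps", list(sq1, sq2), st = 1)
  r <- reslice_structure(s, 0.5, c(0, 0, 0))
  zs <- contour_z(r)
  # at z = 10.5 (tie between 10 and 11) the inferior contour must win
  mid <- r$contours[[which(abs(zs - 10.5) < 1e-9)]]
  expect_equal(max(mid$vertices[, 1]), 2)
})

test_that("supersampling scheme follows the two-stage subdivision rule", {
  # CT 0.6 x 0.6 x 1 against a 1-mm dose grid: minis must be <= 1/27 mm^3
  sc <- supersampling_scheme(c(0.6, 0.6, 1), c(1, 1, 1))
  expect_true(prod(c(0.6, 0.6, 1) / sc$factor) <= 1 / 27 + 1e-12)
  # 2-mm dose voxels: first stage to <= 1 mm^3, second to <= 8/27 mm^3
  sc2 <- supersampling_scheme(c(2, 2, 2), c(2, 2, 2))
  expect_true(prod(c(2, 2, 2) / sc2$factor) <= 8 / 27 + 1e-12)
  expect_identical(supersampling_scheme(c(1, 1, 1), factor = 5)$factor,
                   rep(5L, 3))
})
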