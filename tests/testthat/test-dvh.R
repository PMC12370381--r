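test_that("interpolated dose lookup satisfies the interpolation identities", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(8, 8, 8))
  vals <- array(runif(prod(g$dims), 10, 30), g$dims)
  d <- dose_grid(g, vals, 30)
  # at a voxel centre both interpolants reproduce the sample exactly
  p <- c(3, 4, 2)
  expected <- vals[4, 5, 3] / 30 * 100
  expect_equal(as.numeric(trilinear_dose(d, p)), expected, tolerance = 1e-12)
  expect_equal(as.numeric(dose_at(d, matrix(p, 1), "cubic")), expected,
               tolerance = 1e-9)
  # midway between two voxels of 40% and 60%: trilinear gives 50%
  v2 <- array(0, c(4, 4, 4)); v2[2, 2, 2] <- 12; v2[3, 2, 2] <- 18
  d2 <- dose_grid(voxel_grid(c(0, 0, 0), c(1, 1, 1), c(4, 4, 4)), v2, 30)
  expect_equal(as.numeric(trilinear_dose(d2, c(1.5, 1, 1))), 50)
  # constant grid: any interior point returns the constant
  d3 <- uniform_dose(70, dims = c(6, 6, 6))
  expect_equal(as.numeric(dose_at(d3, rbind(c(2.2, 3.7, 1.9)), "cubic")), 70,
               tolerance = 1e-9)
  # clamped lookups are flagged
  expect_warning(out <- trilinear_dose(d3, c(-5, 2, 2)), "clamped")
  expect_equal(attr(out, "n_clamped"), 1L)
})

test_that("isodose volumes recover closed forms within 1% at fine DG", {
  cen <- c(15.4, 14.8, 15.3)
  m <- dose_model(R = 5, g = 3, center = cen)
  g <- voxel_grid(c(0, 0, 0), c(0.5, 0.5, 0.5), c(61, 61, 61))
  d <- sample_dose_grid(m, g)
  reg <- eval_region_sphere(cen, isodose_radius(25, m))
  iv <- isodose_volumes(d, c(100, 50), reg)
  expect_lt(abs(iv[["V100"]] / analytic_isodose_volume(100, m) - 1) * 100, 1)
  expect_lt(abs(iv[["V50"]] / analytic_isodose_volume(50, m) - 1) * 100, 1)
})

test_that("isodose volumes are nested and vanish above the grid maximum", {
  cen <- c(15.4, 14.8, 15.3)
  m <- dose_model(R = 5, g = 3, center = cen)
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(31, 31, 31))
  d <- sample_dose_grid(m, g)
  reg <- eval_region_sphere(cen, isodose_radius(25, m))
  iv <- isodose_volumes(d, c(50, 80, 100), reg)
  expect_true(iv[["V50"]] >= iv[["V80"]] && iv[["V80"]] >= iv[["V100"]])
  expect_equal(isodose_volume(d, 200, reg), 0)
  far <- eval_region_sphere(c(500, 500, 500), 5)
  expect_error(isodose_volumes(d, 50, far), "crop box|empty")
})

test_that("DVH of uniform and two-level doses has the expected shape", {
  g <- ct_grid_mm(extent = c(30, 30, 20))
  s <- sphere_fixture(c(14.3, 15.2, 9.6), 10, g)
  d <- uniform_dose(100, dims = c(31, 31, 21))
  curve <- cumulative_dvh(s, d)
  expect_equal(curve$cum_pct[1], 100)
  expect_true(all(diff(curve$cum_pct) <= 1e-12))
  expect_equal(v_at_dose(curve, 100), 100)     # uniform 100%: V100 = 100%
  expect_equal(v_at_dose(curve, 100.2), 0)     # nothing beyond
  expect_equal(d95(curve), 100, tolerance = 0.1)
  # half/half 50% and 150%: a single 50%-volume step
  g2 <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(21, 21, 21))
  vals <- array(0.5 * 30, g2$dims); vals[, , 11:21] <- 1.5 * 30
  d2 <- dose_grid(g2, vals, 30)
  box <- rt_structure("box", list(
    planar_contour(8, rbind(c(4, 4), c(16, 4), c(16, 16), c(4, 16))),
    planar_contour(12, rbind(c(4, 4), c(16, 4), c(16, 16), c(4, 16)))), st = 4)
  cv <- cumulative_dvh(box, d2, interp = "linear")
  expect_equal(v_at_dose(cv, 40), 100, tolerance = 2)
  expect_equal(v_at_dose(cv, 100), 50, tolerance = 3)
  expect_equal(v_at_dose(cv, 160), 0)
})

test_that("D95 and V_dose definitions behave on degenerate curves", {
  d <- uniform_dose(103.39, dims = c(8, 8, 8))
  s <- rt_structure("cube", list(
    planar_contour(2, rbind(c(1, 1), c(5, 1), c(5, 5), c(1, 5))),
    planar_contour(4, rbind(c(1, 1), c(5, 1), c(5, 5), c(1, 5)))), st = 2)
  curve <- cumulative_dvh(s, d, interp = "linear")
  expect_equal(d95(curve), 103.39, tolerance = 0.1)
  expect_equal(v_at_dose(curve, 99), 100)
  # step curve: 96% of volume at >= 101 -> D95 = 101
  step <- structure(list(dose = c(0, 101, 101.1), cum_cm3 = c(1, 0.96, 0),
                         cum_pct = c(100, 96, 0), total_cm3 = 1,
                         bin_width = 0.1), class = "dvh_curve")
  expect_equal(d95(step), 101, tolerance = 0.01)
  # consistency: V(D95) >= 95 - bin
  expect_gte(v_at_dose(curve, d95(curve)), 95 - curve$bin_width)
})

test_that("conformity and gradient indices follow their algebra", {
  expect_equal(conformity_index(1, 1, 1), 1)
  expect_equal(conformity_index(1, 2, 1), 0.5)
  expect_equal(conformity_index(2, 2, 1), 0.25)
  expect_error(conformity_index(1, 1, 1.5), "inconsistent")
  # invariant under common rescaling
  for (k in c(0.1, 3, 42))
    expect_equal(conformity_index(2 * k, 3 * k, 1.5 * k),
                 conformity_index(2, 3, 1.5))
  expect_equal(gradient_index(2, 1), 2)
  expect_equal(gradient_index(1.3, 1.3), 1)
  expect_error(gradient_index(1, 0), "positive")
})

test_that("computed GI matches the closed form on a fine grid", {
  cen <- c(15.4, 14.8, 15.3)
  m <- dose_model(R = 3, g = 3, center = cen)
  g <- voxel_grid(c(0, 0, 0), c(0.5, 0.5, 0.5), c(61, 61, 61))
  d <- sample_dose_grid(m, g)
  reg <- eval_region_sphere(cen, isodose_radius(25, m))
  iv <- isodose_volumes(d, c(100, 50), reg)
  gi <- gradient_index(iv[["V50"]], iv[["V100"]])
  expect_lt(abs(gi / 8 - 1) * 100, 2)   # (r50/r100)^3 = (6/3)^3 = 8
})

test_that("plan indices are internally consistent on a sphere phantom", {
  cen <- c(15.4, 14.8, 15.3)
  g <- ct_grid_mm(extent = c(31, 31, 31))
  s <- sphere_fixture(cen, 10, g)
  m <- dose_model(R = 5, g = 3, center = cen)
  dg <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(32, 32, 32))
  d <- sample_dose_grid(m, dg)
  reg <- eval_region_sphere(cen, isodose_radius(25, m))
  pi_ <- plan_indices(s, d, reg, g)
  expect_lte(pi_$TV_PIV, min(pi_$TV, pi_$PIV) + 1e-12)
  expect_gt(pi_$CI, 0.85)               # conformal by construction
  expect_lte(pi_$CI, 1)
  expect_gte(pi_$GI, 1)
  expect_gte(pi_$V30Gy, 95)             # full coverage by construction
  expect_gte(pi_$D95, 100 - 0.5)
  # GI from the V_dose map equals GI from isodose_volumes (same pass)
  iv <- isodose_volumes(d, c(100, 50), reg)
  expect_equal(pi_$GI, gradient_index(iv[["V50"]], iv[["V100"]]),
               tolerance = 1e-9)
  # V_dose map is non-increasing in level
  expect_true(all(diff(unname(pi_$vdose)) >= -1e-12))
})
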