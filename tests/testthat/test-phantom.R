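test_that("ground-truth bundle manifest is closed-form and centre-independent", {
  b <- make_ground_truth_bundle(diameters = 3, n_per_diameter = 10, seed = 7)
  expect_length(b$targets, 10)
  expect_equal(nrow(b$manifest), 10)
  expect_true(all(abs(b$manifest$volume_cm3 * 1000 - 14.137) < 1e-2))
  b2 <- make_ground_truth_bundle(diameters = 3, n_per_diameter = 10, seed = 8)
  # different seeds move the centres but not the manifest
  c1 <- b$targets[[1]]$structure$analytic$center
  c2 <- b2$targets[[1]]$structure$analytic$center
  expect_false(isTRUE(all.equal(c1, c2)))
  expect_equal(b$manifest[setdiff(names(b$manifest), "target")],
               b2$manifest[setdiff(names(b2$manifest), "target")])
})

test_that("bundle volumes validate against closed forms at the in-house level", {
  b <- make_ground_truth_bundle(diameters = 3, n_per_diameter = 12, seed = 3)
  val <- validate_bundle(b, quantities = "volume")
  expect_lt(mean(abs(val$per_target$d_volume)), 1.4)
  expect_lt(max(abs(val$per_target$d_volume)), 6.5)
})

test_that("every target's evaluation volume contains its 50% isodose", {
  b <- make_ground_truth_bundle(diameters = c(3, 10), n_per_diameter = 3, seed = 5)
  for (t in b$targets) {
    expect_gt(t$region$radius, isodose_radius(50, t$model))
    expect_equal(t$region$radius, isodose_radius(25, t$model))
    expect_equal(t$region$center, t$model$center)
  }
})

test_that("clinical-like cases are deterministic given spec + seed", {
  spec <- clinical_case_spec(n_lesions = 3, seed = 42)
  b1 <- make_clinical_like_case(spec)
  b2 <- make_clinical_like_case(spec)
  expect_identical(b1, b2)
  b3 <- make_clinical_like_case(clinical_case_spec(n_lesions = 3, seed = 43))
  expect_false(identical(b1$targets[[1]]$structure, b3$targets[[1]]$structure))
})

test_that("clinical-like lesions are covered and separated", {
  spec <- clinical_case_spec(n_lesions = 4, seed = 9)
  b <- make_clinical_like_case(spec)
  cens <- t(vapply(b$targets, function(t) t$model$center, numeric(3)))
  Rs <- vapply(b$targets, function(t) t$model$R, 0)
  for (i in 1:3) for (j in (i + 1):4) {
    d <- sqrt(sum((cens[i, ] - cens[j, ])^2))
    # no lesion's prescription isodose intrudes into another's shell
    expect_gt(d, Rs[i] + 15 + Rs[j])
  }
  # coverage: every contour vertex of a lesion lies inside its own
  # prescription isodose (dose model plateau covers the whole blob)
  for (t in b$targets) {
    verts <- do.call(rbind, lapply(t$structure$contours, function(cc)
      cbind(cc$vertices, cc$z)))
    doses <- radial_dose(srsdvh:::model_radius(verts, t$model), t$model)
    expect_true(all(doses >= 100 - 1e-9))
  }
})

test_that("single fine-grid lesion recovers its closed-form V100 within 2%", {
  spec <- clinical_case_spec(n_lesions = 1, diameters = 30, irregularity = 0,
                             bath_level = 0, seed = 4)
  b <- make_clinical_like_case(spec, dose_spacing = c(0.75, 0.75, 0.75))
  d <- target_dose(b, 1, dg = 0.75)
  iv <- isodose_volume(d, 100, b$targets[[1]]$region)
  expect_lt(abs(iv / b$manifest$v100_cm3[1] - 1) * 100, 2)
})

test_that("seed streams stay within 32-bit range and separate", {
  s <- vapply(0:200, function(k) derive_seed(123456, k), 0L)
  expect_true(all(s >= 0 & s < 2^31))
  expect_equal(length(unique(s)), 201L)
})
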