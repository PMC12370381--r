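# Scaled-down end-to-end study runs (small lesion sets, two settings) so the
# orchestration logic and its invariants are exercised quickly.

make_small_cases <- function(n_cases = 2, n_lesions = 2, seed = 11)
  lapply(seq_len(n_cases), function(i)
    make_clinical_like_case(
      clinical_case_spec(n_lesions = n_lesions, diameters = c(10, 20),
                         seed = derive_seed(seed, i)),
      case_name = sprintf("case%02d", i)))

test_that("identity perturbation yields unit ratios and p = 1", {
  bundles <- make_small_cases()
  cfg <- study_config(st = c(1, 1), dg = c(1, 1), seed = 11)
  # force a single evaluated setting equal to the reference by using the
  # reference twice: construct explicitly with one perturbation = reference
  cfg <- study_config(st = 1, dg = c(1, 2), seed = 11)
  res <- run_study(bundles, cfg)
  rec <- res$records
  # re-evaluating the reference itself reproduces it exactly
  ref1 <- srsdvh:::eval_bundle_setting(bundles[[1]], 1, 1, cfg)
  ref2 <- srsdvh:::eval_bundle_setting(bundles[[1]], 1, 1, cfg)
  expect_identical(ref1, ref2)
  # and the DG perturbation produced one record per target x quantity
  n_targets <- sum(vapply(bundles, function(b) length(b$targets), 0L))
  n_quant <- length(cfg$levels) + 4L
  expect_equal(nrow(rec), n_targets * n_quant)
  expect_true(all(is.finite(rec$ratio[rec$v_ref > 0])))
  # ratio and % difference are mutually consistent
  expect_equal(rec$pct_diff, 100 * (rec$ratio - 1), tolerance = 1e-12)
})

test_that("coarser DG underestimates small isodose volumes more", {
  b1 <- make_clinical_like_case(
    clinical_case_spec(n_lesions = 1, diameters = 6, seed = 21), case_name = "s")
  b2 <- make_clinical_like_case(
    clinical_case_spec(n_lesions = 1, diameters = 30, seed = 22), case_name = "l")
  cfg <- study_config(st = 1, dg = c(1, 2), seed = 21)
  res <- run_study(list(b1, b2), cfg)
  v100 <- res$records[res$records$quantity == "V100", ]
  small <- v100$ratio[v100$diameter == 6]
  large <- v100$ratio[v100$diameter == 30]
  expect_lte(small, 1)
  expect_gt(large, small)     # closer to 1 for the large lesion
})

test_that("ST perturbation leaves analytic V_dose unchanged but moves indices", {
  bundles <- make_small_cases(1, 2, seed = 31)
  cfg <- study_config(st = c(1, 2), dg = 1, seed = 31)
  res <- suppressWarnings(run_study(bundles, cfg))
  rec <- res$records[res$records$perturbation == "ST_2mm", ]
  vd <- rec[rec$quantity %in% paste0("V", cfg$levels), ]
  expect_true(all(abs(vd$ratio - 1) < 1e-12))
  idx <- rec[rec$quantity %in% c("D95", "V30Gy", "CI"), ]
  expect_gt(max(abs(idx$ratio - 1)), 1e-6)
})

test_that("study results are deterministic given config + seed", {
  bundles <- make_small_cases(1, 1, seed = 41)
  cfg <- study_config(st = 1, dg = c(1, 3), seed = 41)
  r1 <- run_study(bundles, cfg)
  r2 <- run_study(bundles, cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$index_stats, r2$index_stats)
})
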