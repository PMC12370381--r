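test_that("spearman ratio analysis: monotone, degenerate and exact cases", {
  x <- c(0.2, 0.8, 1.5, 3, 7, 12)
  expect_equal(spearman_ratio_analysis(x, x^2)$rho, 1)
  expect_warning(out <- spearman_ratio_analysis(x, rep(1, 6)), "constant")
  expect_equal(out$rho, 0)
  # exact permutation p equals full enumeration over all 720 permutations
  set.seed(1)
  y <- c(0.85, 0.9, 1.02, 0.97, 1.01, 0.99)
  got <- spearman_ratio_analysis(x, y)
  expect_equal(got$method, "exact permutation")
  expect_equal(got$p, spearman_exact_p(x, y), tolerance = 1e-12)
  # and for a second draw with ties in ranks avoided
  y2 <- c(1.2, 0.7, 1.05, 0.93, 1.11, 0.88)
  expect_equal(spearman_ratio_analysis(x, y2)$p, spearman_exact_p(x, y2),
               tolerance = 1e-12)
})

test_that("power-law fit recovers noise-free parameters to 1e-6", {
  x <- c(0.1, 0.25, 0.6, 1.2, 2.5, 5, 9, 14)
  truth <- list(a = -0.5, b = -1, c = 1.0)
  y <- truth$a * x^truth$b + truth$c
  fit <- fit_power_law(x, y)
  expect_equal(fit$a, truth$a, tolerance = 1e-6)
  expect_equal(fit$b, truth$b, tolerance = 1e-6)
  expect_equal(fit$c, truth$c, tolerance = 1e-6)
  expect_lt(fit$nrmse, 1e-6)
  # a second parameter set, shallower exponent
  y2 <- -0.08 * x^-0.35 + 0.99
  fit2 <- fit_power_law(x, y2)
  expect_equal(fit2$b, -0.35, tolerance = 1e-6)
})

test_that("power-law fit guards the degenerate constant case", {
  x <- c(0.5, 1, 2, 4, 8)
  fit <- fit_power_law(x, rep(0.97, 5))
  expect_lt(abs(fit$fitted(3) - 0.97), 1e-8)
  expect_equal(fit$nrmse, 0)
})

test_that("noisy power-law fit has NRMSE of the expected order", {
  set.seed(3)
  x <- exp(runif(60, log(0.1), log(15)))
  y <- -0.05 * x^-0.8 + 1 + rnorm(60, 0, 0.02)
  fit <- fit_power_law(x, y)
  expect_gt(fit$nrmse, 0.005)
  expect_lt(fit$nrmse, 0.2)     # order 1e-2, comparable to the study fits
})

test_that("signed-rank comparison matches the exact enumeration oracle", {
  # constant shift, n = 10: exact two-sided p = 2 / 2^10
  ref <- c(10, 11, 12, 13, 14, 15, 16, 17, 18, 19)
  ev <- ref + 0.5
  got <- paired_compare(ref, ev)
  expect_equal(got$p, 2 / 2^10, tolerance = 1e-12)
  expect_equal(got$p, signed_rank_exact_p(ev - ref), tolerance = 1e-12)
  # random paired sets, n <= 12: enumeration oracle equivalence
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    r <- rnorm(n)
    e <- r + rnorm(n, 0.3, 0.7)
    e[abs(e - r) < 1e-6] <- r[abs(e - r) < 1e-6] + 0.1
    expect_equal(paired_compare(r, e)$p, signed_rank_exact_p(e - r),
                 tolerance = 1e-10, label = sprintf("draw %d (n=%d)", rep, n))
  }
})

test_that("signed-rank comparison handles identity and antisymmetry", {
  ref <- c(1, 2, 3, 4, 5, 6)
  same <- paired_compare(ref, ref)
  expect_equal(same$p, 1)
  expect_match(same$note, "zero")
  anti <- paired_compare(ref, ref + c(-3, -2, -1, 1, 2, 3))
  expect_gt(anti$p, 0.9)
})

test_that("effect size and required n follow the paired approximation", {
  d1 <- effect_size_and_n(c(0, 1, 2))          # mean 1, sd 1
  expect_equal(d1$d, 1)
  # d = 1.03 at alpha 0.05, power 0.8: about 8 cases required
  diffs <- c(0.5, 1.5) * 1.03 / 1              # mean 1.03, sd ~0.707 -> scale
  x <- c(-1, 1) ; x <- x / sd(x) * 1           # unit sd
  x <- x + 1.03                                # mean 1.03, sd 1... n = 2 though
  es <- effect_size_and_n(x)
  expect_equal(es$d, 1.03, tolerance = 1e-9)
  expect_lte(abs(es$n_required - 8), 1)
  # scale invariance
  y <- rnorm(10)
  expect_equal(effect_size_and_n(y)$d, effect_size_and_n(2 * y)$d)
  expect_equal(effect_size_and_n(y)$n_required,
               effect_size_and_n(2 * y)$n_required)
  expect_error(effect_size_and_n(c(1, 1, 1)), "zero-variance")
})
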