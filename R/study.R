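#' Configuration of the slice-thickness / dose-grid perturbation study
#'
#' @param st slice thicknesses to evaluate, mm (reference must be included).
#' @param dg dose-grid resolutions to evaluate, mm (reference included).
#' @param levels V_dose isodose levels, % of prescription.
#' @param ref_st,ref_dg the reference discretisation, mm.
#' @param alpha significance level for the signed-rank comparisons.
#' @param power target power for the required-sample-size calculation.
#' @param seed master seed.
#' @return object of class `study_config`.
#' @export
study_config <- function(st = c(1, 1.5, 2), dg = c(1, 2, 3),
                         levels = c(110, 100, 98, 95, 80, 50),
                         ref_st = 1, ref_dg = 1, alpha = 0.05, power = 0.8,
                         seed = 1) {
  stopifnot(ref_st %in% st, ref_dg %in% dg,
            alpha > 0, alpha < 1, power > 0, power < 1)
  structure(list(st = st, dg = dg, levels = levels, ref_st = ref_st,
                 ref_dg = ref_dg, alpha = alpha, power = power, seed = seed),
            class = "study_config")
}

# Evaluate every target of a bundle at one (st, dg) setting.
# Returns a data.frame: one row per target with indices, plus V_dose columns.
eval_bundle_setting <- function(bundle, st, dg, config, interp = "cubic") {
  rows <- vector("list", length(bundle$targets))
  for (i in seq_along(bundle$targets)) {
    t <- bundle$targets[[i]]
    struct <- t$structure
    if (st != bundle$ct_grid$spacing[3])
      struct <- reslice_structure(struct, st, bundle$ct_grid$origin)
    dose <- target_dose(bundle, i, dg = dg)
    region <- t$region
    ct_grid <- bundle$ct_grid
    if (st != ct_grid$spacing[3])
      ct_grid <- voxel_grid(ct_grid$origin,
                            c(ct_grid$spacing[1:2], st),
                            c(ct_grid$dims[1:2],
                              ceiling(ct_grid$dims[3] * ct_grid$spacing[3] / st)))
    pi_ <- plan_indices(struct, dose, region, ct_grid,
                        levels = config$levels, interp = interp)
    vd <- pi_$vdose[paste0("V", config$levels)]
    rows[[i]] <- cbind(
      data.frame(target = t$structure$name, diameter = t$diameter,
                 st = st, dg = dg,
                 TV = pi_$TV, PIV = pi_$PIV, TV_PIV = pi_$TV_PIV,
                 CI = pi_$CI, GI = pi_$GI, D95 = pi_$D95, V30Gy = pi_$V30Gy),
      as.data.frame(as.list(vd)))
  }
  do.call(rbind, rows)
}

#' Run the discretisation study
#'
#' For every bundle target, evaluates the plan-quality indices and V_dose
#' volumes at the reference discretisation (ref ST, ref DG) and at each
#' perturbed setting: coarser dose grids (analytic re-evaluation at the
#' coarser voxel centres, the recalculation semantics) with the reference
#' ST, and thicker slices (structures resliced on the common origin) with
#' the reference DG. Produces paired comparison records (ratios and local %
#' differences against the reference), the Spearman ratio analysis and
#' power-law fit per perturbation, and per-diameter-group signed-rank
#' statistics for each index.
#'
#' @param bundles a `phantom_bundle` or list of them (e.g. one per
#'   clinical-like case).
#' @param config a [study_config()].
#' @param interp dose interpolant (see [dose_at()]); the study defaults to
#'   `"linear"`, the plain mini-voxel interpolant of a TPS DVH tool, whose
#'   discretisation bias the study is designed to expose. The high-accuracy
#'   `"cubic"` interpolant is the validation instrument.
#' @return object of class `study_result` with `records` (tidy data.frame:
#'   one row per target x quantity x perturbation), `reference` and
#'   `evaluations` data.frames, `ratio_analysis` (per perturbation:
#'   Spearman + power-law [fit_power_law()] on V_dose ratios), and
#'   `index_stats` (per perturbation x diameter group x index:
#'   [paired_compare()] + [effect_size_and_n()]).
#' @export
run_study <- function(bundles, config = study_config(), interp = "linear") {
  if (inherits(bundles, "phantom_bundle")) bundles <- list(bundles)
  dg_alt <- setdiff(config$dg, config$ref_dg)
  st_alt <- setdiff(config$st, config$ref_st)
  settings <- data.frame(
    st = c(config$ref_st, rep(config$ref_st, length(dg_alt)), st_alt),
    dg = c(config$ref_dg, dg_alt, rep(config$ref_dg, length(st_alt))))
  evals <- list()
  for (s in seq_len(nrow(settings))) {
    per_bundle <- lapply(bundles, eval_bundle_setting,
                         st = settings$st[s], dg = settings$dg[s],
                         config = config, interp = interp)
    evals[[s]] <- do.call(rbind, per_bundle)
  }
  ref <- evals[[1]]
  vd_cols <- paste0("V", config$levels)
  idx_cols <- c("D95", "V30Gy", "CI", "GI")
  records <- list()
  ratio_analysis <- list()
  index_stats <- list()
  for (s in seq_len(nrow(settings))[-1]) {
    ev <- evals[[s]]
    pert <- if (settings$dg[s] != config$ref_dg)
      sprintf("DG_%gmm", settings$dg[s]) else sprintf("ST_%gmm", settings$st[s])
    stopifnot(identical(ev$target, ref$target))
    for (q in c(vd_cols, idx_cols)) {
      ok <- ref[[q]] > 0
      records[[length(records) + 1L]] <- data.frame(
        target = ref$target, diameter = ref$diameter, perturbation = pert,
        quantity = q, v_ref = ref[[q]], v_eval = ev[[q]],
        ratio = ifelse(ok, ev[[q]] / ref[[q]], NA_real_),
        pct_diff = ifelse(ok, 100 * (ev[[q]] / ref[[q]] - 1), NA_real_))
    }
    # pooled V_dose ratio analysis vs reference volume
    x <- unlist(ref[vd_cols], use.names = FALSE)
    y <- unlist(ev[vd_cols], use.names = FALSE) / x
    keep <- is.finite(x) & is.finite(y) & x > 0
    ra <- list(perturbation = pert,
               spearman = if (sum(keep) >= 3)
                 spearman_ratio_analysis(x[keep], y[keep])
               else list(rho = NA_real_, p = NA_real_, n = sum(keep),
                         method = "too few pairs"),
               fit = if (sum(keep) >= 5) fit_power_law(x[keep], y[keep]) else NULL)
    ratio_analysis[[pert]] <- ra
    for (D in sort(unique(ref$diameter))) {
      sel <- ref$diameter == D
      for (q in idx_cols) {
        pc <- if (sum(sel) >= 5) paired_compare(ref[[q]][sel], ev[[q]][sel])
          else list(median = stats::median(ev[[q]][sel]), min = min(ev[[q]][sel]),
                    max = max(ev[[q]][sel]), p = NA_real_)
        diffs <- ev[[q]][sel] - ref[[q]][sel]
        es <- if (length(diffs) >= 2 && stats::sd(diffs) > 0)
          effect_size_and_n(diffs, config$alpha, config$power)
        else list(d = NA_real_, n_required = NA_integer_)
        index_stats[[length(index_stats) + 1L]] <- data.frame(
          perturbation = pert, diameter = D, index = q,
          median = pc$median, min = pc$min, max = pc$max, p = pc$p,
          effect_size = es$d, n_required = es$n_required,
          median_pct_diff = stats::median(100 * (ev[[q]][sel] / ref[[q]][sel] - 1)))
      }
    }
  }
  structure(list(records = do.call(rbind, records), reference = ref,
                 evaluations = stats::setNames(
                   evals, c("reference",
                            sprintf("%s", vapply(seq_len(nrow(settings))[-1], function(s)
                              if (settings$dg[s] != config$ref_dg)
                                sprintf("DG_%gmm", settings$dg[s])
                              else sprintf("ST_%gmm", settings$st[s]), "")))),
                 ratio_analysis = ratio_analysis,
                 index_stats = do.call(rbind, index_stats),
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d targets, perturbations: %s\n",
              nrow(x$reference), paste(names(x$ratio_analysis), collapse = ", ")))
  for (nm in names(x$ratio_analysis)) {
    ra <- x$ratio_analysis[[nm]]
    cat(sprintf("  %s: Spearman rho %.3f (p %.3g)%s\n", nm,
                ra$spearman$rho, ra$spearman$p,
                if (!is.null(ra$fit)) sprintf(", fit NRMSE %.3f", ra$fit$nrmse) else ""))
  }
  invisible(x)
}

#' Spearman rank correlation of V_dose ratios against reference volumes
#'
#' rho on (V_ref, ratio) pairs; the p-value is computed by exact permutation
#' enumeration for n <= 9 and by the t approximation otherwise. When either
#' variable is constant (rho undefined), rho is reported as 0 with a
#' warning.
#'
#' @param x reference values (e.g. V_dose(ref), cm^3).
#' @param y ratios V_dose(eval)/V_dose(ref).
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman_ratio_analysis <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho undefined, reported as 0")
    return(list(rho = 0, p = 1, n = length(x), method = "degenerate"))
  }
  n <- length(x)
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= 9) {
    rxc <- rank(x) - (n + 1) / 2
    ryc <- rank(y) - (n + 1) / 2
    perms <- permutations_of(n)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- (matrix(ryc[perms], nrow(perms), n) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

# All permutations of 1..n as an (n!) x n matrix (n <= 9).
permutations_of <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Power-law fit of V_dose ratios against reference volume
#'
#' Least-squares fit of `y = a * x^b + c`. For fixed b the model is linear
#' in (a, c), so b is profiled on a log-spaced grid (and refined with
#' `optimize` plus a Levenberg-Marquardt polish via minpack.lm); the best
#' sum of squares wins. The fit error is reported as NRMSE, the RMSE
#' normalised by the range of y (0 when the range degenerates).
#'
#' @param x reference volumes (> 0), cm^3.
#' @param y ratios.
#' @param b_grid profile grid for the exponent.
#' @return object of class `ratio_fit`: `a`, `b`, `c`, `nrmse`, `rmse`,
#'   `fitted` function.
#' @export
fit_power_law <- function(x, y, b_grid = -exp(seq(log(1e-3), log(3), length.out = 60))) {
  stopifnot(length(x) == length(y), length(x) >= 5, all(x > 0))
  b_grid <- sort(unique(c(b_grid, -b_grid, -1, -0.5, 0.5, 1)))
  sse_for <- function(b) {
    xb <- x^b
    fit <- stats::lm.fit(cbind(xb, 1), y)
    list(sse = sum(fit$residuals^2), a = fit$coefficients[1],
         c = fit$coefficients[2])
  }
  prof <- lapply(b_grid, sse_for)
  sses <- vapply(prof, `[[`, 0, "sse")
  best <- which.min(sses)
  b0 <- b_grid[best]
  lo <- b_grid[max(best - 1, 1)]; hi <- b_grid[min(best + 1, length(b_grid))]
  if (lo < hi) {
    op <- stats::optimize(function(b) sse_for(b)$sse, c(lo, hi))
    if (op$objective < sses[best]) b0 <- op$minimum
  }
  sol <- sse_for(b0)
  a0 <- unname(sol$a); c0 <- unname(sol$c)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^b + c,
                      start = list(a = a0, b = b0, c = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (sum(stats::resid(fit)^2) <= sol$sse + 1e-12) {
      a0 <- unname(cf["a"]); b0 <- unname(cf["b"]); c0 <- unname(cf["c"])
      sol$sse <- sum(stats::resid(fit)^2)
    }
  }
  if (!is.finite(sol$sse)) stop("power-law fit failed to converge")
  rmse <- sqrt(sol$sse / length(y))
  rng <- diff(range(y))
  structure(list(a = a0, b = b0, c = c0, rmse = rmse,
                 nrmse = if (rng > 0) rmse / rng else 0,
                 n = length(y),
                 fitted = function(xx) a0 * xx^b0 + c0),
            class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("ratio_fit: y = %.4g * x^%.4g + %.4g (n = %d, NRMSE = %.4g)\n",
              x$a, x$b, x$c, x$n, x$nrmse))
  invisible(x)
}

#' Paired comparison by the Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of evaluated against reference values, paired
#' by target: zero differences are dropped, the exact null distribution
#' (midrank ties included) is enumerated by dynamic programming for up to 25
#' nonzero pairs, and the normal approximation with continuity correction is
#' used beyond. Also returns summary statistics of the evaluated set.
#' All-zero differences give p = 1 with a note.
#'
#' @param ref,eval paired numeric vectors (equal length >= 5).
#' @return list with `median`, `min`, `max` (of `eval`), `p`, `n`, `note`.
#' @export
paired_compare <- function(ref, eval) {
  stopifnot(length(ref) == length(eval), length(ref) >= 5)
  d <- eval - ref
  note <- NULL
  nz <- d[d != 0]
  if (!length(nz)) {
    p <- 1
    note <- "all paired differences are zero"
  } else if (length(nz) <= 25) {
    p <- exact_signed_rank_p(nz)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(eval, ref, paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value)
  }
  list(median = stats::median(eval), min = min(eval), max = max(eval),
       p = p, n = length(d), note = note)
}

# Exact two-sided signed-rank p-value for nonzero differences, tied ranks
# included: the null distribution of W+ is built by dynamic programming on
# the generating function prod_i (1 + z^{2 r_i}) (doubled ranks are integers
# even under midrank ties).
exact_signed_rank_p <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))
  w_obs <- sum(r2[d > 0])
  tot <- sum(r2)
  coef <- numeric(tot + 1L)
  coef[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), coef[seq_len(tot + 1L - r)])
    coef <- coef + shifted
  }
  probs <- coef / 2^length(d)
  dev <- abs(seq(0L, tot) - tot / 2)
  min(1, sum(probs[dev >= abs(w_obs - tot / 2) - 1e-9]))
}

#' Paired effect size and required sample size
#'
#' Cohen's d for paired data, `d = mean(diff) / sd(diff)`, and the total
#' sample size required to detect it with a two-sided signed-rank test at
#' significance `alpha` and the given power: the paired-test normal
#' approximation `n = (z_{1-alpha/2} + z_{power})^2 / d^2`, inflated by the
#' signed-rank asymptotic relative efficiency 0.955 and rounded up.
#'
#' @param differences paired differences (length >= 2, sd > 0).
#' @param alpha significance level.
#' @param power target power.
#' @return list with `d` and `n_required`.
#' @export
effect_size_and_n <- function(differences, alpha = 0.05, power = 0.8) {
  stopifnot(length(differences) >= 2)
  s <- stats::sd(differences)
  if (s == 0) stop("zero-variance differences: effect size undefined")
  d <- mean(differences) / s
  n <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / d^2 / 0.955
  list(d = d, n_required = as.integer(ceiling(n)))
}
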