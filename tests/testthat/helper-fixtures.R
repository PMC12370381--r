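# Shared fixtures, built in code.

unit_square <- function(z = 0)
  planar_contour(z, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))

# 10 x 10 mm square contour on a single slice; the centre is kept off the
# sub-sample lattice so the boundary tie rule (edges count as inside) does
# not align with a whole ring of sub-points.
square_structure <- function(z = 0, side = 10, st = 1, name = "square",
                             center = c(5.03, 4.97)) {
  half <- side / 2
  rt_structure(name, list(planar_contour(
    z, rbind(center + c(-half, -half), center + c(half, -half),
             center + c(half, half), center + c(-half, half)))), st = st)
}

# small CT-like grid centred loosely on the origin cell
ct_grid_mm <- function(extent = c(30, 30, 30), spacing = c(0.6, 0.6, 1))
  voxel_grid(c(0, 0, 0), spacing, ceiling(extent / spacing))

sphere_fixture <- function(center, D, grid = ct_grid_mm(), ...)
  sphere_structure(center, D, grid_axes(grid)$z, st = grid$spacing[3], ...)

sphere_inside_fn <- function(center, D) {
  function(p) rowSums(sweep(p, 2, center)^2) <= (D / 2)^2
}

# uniform dose grid at a given % of a 30 Gy prescription
uniform_dose <- function(pct, spacing = c(1, 1, 1), dims = c(40, 40, 40),
                         prescription = 30) {
  g <- voxel_grid(c(0, 0, 0), spacing, dims)
  dose_grid(g, array(pct / 100 * prescription, dims), prescription)
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (independent oracle; no ties/zeros assumed).
signed_rank_exact_p <- function(d) {
  stopifnot(all(d != 0), length(d) <= 12)
  r <- rank(abs(d))
  n <- length(d)
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.numeric(signs %*% r)
  EW <- n * (n + 1) / 4
  min(1, mean(abs(W_all - EW) >= abs(W_obs - EW) - 1e-12))
}

# Exact Spearman permutation p-value by full enumeration (n <= 7 here).
spearman_exact_p <- function(x, y) {
  n <- length(x)
  rho_obs <- cor(x, y, method = "spearman")
  perms <- all_perms(n)
  rhos <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1)))
  }))
}
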