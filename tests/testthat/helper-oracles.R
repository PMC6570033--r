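# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: closed-form normal equations for OLS,
# dense-grid bisection for the speciation root, and an SVD Procrustes
# alignment for comparing factor loadings.

# Closed-form OLS via the normal equations (X'X)^-1 X'y.
ols_oracle <- function(X, y) {
  X <- cbind(intercept = 1, as.matrix(X))
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Free-ligand concentration by brute-force grid refinement of the ligand
# balance; mirrors the model definition but not the solver.
speciate_grid_oracle <- function(totals, params, n_grid = 1e6) {
  k <- c(cd = params$k_cd, ca = params$k_ca, mg = params$k_mg,
         h = params$k_h)
  s <- c(cd = 1, ca = 1, mg = 1, h = 2)
  totals <- unlist(totals)[names(k)]
  balance <- function(L) {
    free <- totals / (1 + s * k * L / 1000)
    L * (1 + sum(s * k * free / 1000)) - params$l0
  }
  grid <- seq(0, params$l0, length.out = n_grid)
  vals <- vapply(grid, balance, numeric(1))
  i <- which(vals >= 0)[1]          # balance is strictly increasing
  lo <- grid[max(i - 1, 1)]
  hi <- grid[i]
  for (iter in 1:60) {              # bisection within the bracketing cell
    mid <- (lo + hi) / 2
    if (balance(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Frobenius distance between two loading matrices after an orthogonal
# Procrustes alignment (and column rescaling-free): measures recovery of a
# factor structure up to rotation and sign.
procrustes_distance <- function(A, B) {
  sv <- svd(t(B) %*% A)
  R <- sv$v %*% t(sv$u)
  sqrt(sum((A %*% R - B)^2) / length(B))
}

# Two-block factor structure: p variables split in two halves, each half
# loading lambda on its own orthogonal factor plus unique noise.
two_block_loadings <- function(p = 8, lambda = 0.9) {
  L <- matrix(0, p, 2)
  L[seq_len(p / 2), 1] <- lambda
  L[(p / 2 + 1):p, 2] <- lambda
  rownames(L) <- paste0("v", seq_len(p))
  L
}

simulate_factor_data <- function(n, loadings, noise = 0.1, seed = 1) {
  set.seed(seed)
  p <- nrow(loadings)
  f <- matrix(rnorm(n * 2), n, 2)
  x <- f %*% t(loadings) + noise * matrix(rnorm(n * p), n, p)
  colnames(x) <- rownames(loadings)
  as.data.frame(x)
}

# Canonical biotic ligand truth used by the recovery tests: moderate,
# well-conditioned affinities and totals.
canonical_blm_truth <- function() {
  blm_parameters(k_cd = 2000, k_ca = 600, k_mg = 600, k_h = 600,
                 ca0 = 1, mg0 = 1, h0 = 1, l0 = 5)
}

blm_recovery_errors <- function(fit, truth, k_ratios_truth) {
  r <- vapply(fit$stage1, `[[`, numeric(1), "k_ratio")
  tot <- vapply(fit$stage1, `[[`, numeric(1), "total0")
  est <- c(r_ca = r[["ca"]], r_mg = r[["mg"]], r_h = r[["h"]],
           t0_ca = tot[["ca"]], t0_mg = tot[["mg"]], t0_h = tot[["h"]],
           l0 = fit$stage2$l0, k_cd = fit$stage2$k_cd)
  tru <- c(r_ca = k_ratios_truth[["ca"]], r_mg = k_ratios_truth[["mg"]],
           r_h = k_ratios_truth[["h"]], t0_ca = truth$ca0,
           t0_mg = truth$mg0, t0_h = truth$h0, l0 = truth$l0,
           k_cd = truth$k_cd)
  abs(est - tru) / tru
}

load_table1 <- function() {
  suppressWarnings(read_soil_table(cadsoil_file("table1_soils.csv")))
}

load_table3 <- function() {
  read_spiked_table(cadsoil_file("table3_cations.csv"))
}
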