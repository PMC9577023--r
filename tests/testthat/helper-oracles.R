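# Independent oracles used across the test files.

# Exact fGn/FBM sampling through the Cholesky factor of the closed-form
# covariance matrix: a generation route independent of the production
# Davies-Harte / Hosking samplers. Returns an n_paths x n_steps matrix of
# path values B(t_1)..B(t_n) (the t = 0 point, identically 0, is omitted).
chol_fbm_paths <- function(n_paths, params) {
  tt <- params$dt * seq_len(params$n_steps)
  C <- outer(tt, tt, function(a, b) fbm_covariance(a, b, params))
  R <- chol(C)
  Z <- matrix(stats::rnorm(n_paths * length(tt)), n_paths)
  Z %*% R
}

# Matrix of per-path values from repeated production 1-D generation.
sample_fbm_matrix <- function(n_paths, params) {
  t(vapply(seq_len(n_paths),
           function(i) fbm_1d(params, seed = NULL)$values[-1, 1],
           numeric(params$n_steps)))
}

# Elementwise z-scores of an empirical covariance against the closed form.
# Var(C_hat_ij) for Gaussian data is (C_ii C_jj + C_ij^2) / n.
cov_zscores <- function(emp, theo, n_paths) {
  se <- sqrt((outer(diag(theo), diag(theo)) + theo^2) / n_paths)
  (emp - theo) / se
}
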