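# Independent oracles used across the suite. These deliberately use only
# brute force / numerical quadrature, never the code paths they check.

# Minimum RMSD over a dense grid of rotations (Euler z-y-z angles) after
# centering both coordinate sets. Oracle for Kabsch superposition.
grid_min_rmsd <- function(A, B, n_grid = 40) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  angs <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  betas <- seq(0, pi, length.out = n_grid %/% 2)
  rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                                sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0,
                                -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
  best <- Inf
  for (a in angs) for (b in betas) for (g in angs) {
    R <- rot_z(a) %*% rot_y(b) %*% rot_z(g)
    v <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
    if (v < best) best <- v
  }
  best
}

# Numerical quadrature of the product of two gaussian densities.
quad_gauss_overlap <- function(mu1, s1, mu2, s2) {
  f <- function(z) stats::dnorm(z, mu1, s1) * stats::dnorm(z, mu2, s2)
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-12)$value
}

# A tiny deterministic flat ensemble for dimension bookkeeping tests.
toy_flat <- function(F = 4, p = 6, seed = 99) {
  set.seed(seed)
  flat_ensemble(matrix(rnorm(F * p), F, p))
}
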