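test_that("projected densities integrate to one and match simple cases", {
  d <- projected_density(c(-1, 1), "gaussian")
  expect_equal(d$mu, 0)
  expect_equal(d$sigma, 1)           # population convention
  set.seed(1)
  z <- rnorm(1e5)
  d2 <- projected_density(z, "gaussian")
  expect_equal(d2$mu, 0, tolerance = 0.02)
  expect_equal(d2$sigma, 1, tolerance = 0.02)
  expect_error(projected_density(rep(2, 10), "gaussian"), "degenerate")
  # constant samples under the histogram model: one bin at density 1/width
  h <- projected_density(rep(2, 10), "histogram")
  occ <- which(h$density > 0)
  expect_length(occ, 1L)
  expect_equal(h$density[occ], 1 / diff(h$breaks)[occ])
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-12)
})

test_that("gaussian overlap matches numerical quadrature and is symmetric", {
  set.seed(2)
  for (i in 1:20) {
    mu <- rnorm(2, 0, 3); s <- runif(2, 0.2, 3)
    z1 <- rnorm(500, mu[1], s[1]); z2 <- rnorm(500, mu[2], s[2])
    d1 <- projected_density(z1); d2 <- projected_density(z2)
    expect_equal(overlap(z1, z2),
                 quad_gauss_overlap(d1$mu, d1$sigma, d2$mu, d2$sigma),
                 tolerance = 1e-8)
  }
  set.seed(3)
  a <- rnorm(1000); b <- rnorm(1000, 4)
  expect_identical(overlap(a, b), overlap(b, a))
  expect_equal(overlap(a, b, "histogram"), overlap(b, a, "histogram"))
})

test_that("random unit vectors are normalized, seeded, and sphere-uniform", {
  set.seed(4)
  V <- random_unit_vectors(7, 100)
  expect_equal(sqrt(rowSums(V^2)), rep(1, 100), tolerance = 1e-12)
  set.seed(5); A <- random_unit_vectors(3, 10)
  set.seed(5); B <- random_unit_vectors(3, 10)
  expect_identical(A, B)
  set.seed(6)
  M <- random_unit_vectors(3, 1e5)
  expect_lt(max(abs(colMeans(M))), 0.02)
})

test_that("a single scan finds a planted axis and never worsens the random stage", {
  set.seed(7)
  p1 <- cbind(rnorm(800, 5, 1), matrix(rnorm(800 * 3), 800, 3))
  p2 <- cbind(rnorm(800, -5, 1), matrix(rnorm(800 * 3), 800, 3))
  res <- run_scan(p1, p2, n_vectors = 200)
  expect_equal(sqrt(sum(res$vector^2)), 1, tolerance = 1e-10)
  expect_gt(abs(res$vector[1]), 0.99)
  # the returned overlap is what the returned vector achieves
  z1 <- as.vector(p1 %*% res$vector); z2 <- as.vector(p2 %*% res$vector)
  expect_equal(res$overlap, overlap(z1, z2), tolerance = 1e-9)
})

test_that("the separation search recovers a planted direction", {
  gg <- gen_two_gaussian_ensembles(dim = 30, n_frames = 1500, gap = 8, seed = 8)
  sr <- search_separation_rc(gg$ens1, gg$ens2, d = 6, n_scans = 10,
                             n_vectors = 150, seed = 9)
  expect_equal(sqrt(sum(sr$n_hat^2)), 1, tolerance = 1e-10)
  expect_gt(abs(sum(sr$n_hat * gg$separation_vector)), 0.99)
  # converged scans: final per-coordinate variances are small
  expect_lt(max(sr$variance_trace[nrow(sr$variance_trace), ]), 1e-3)
  # swapping ensemble order flips at most the sign
  sr2 <- search_separation_rc(gg$ens2, gg$ens1, d = 6, n_scans = 10,
                              n_vectors = 150, seed = 9)
  expect_equal(abs(sum(sr$n_hat * sr2$n_hat)), 1, tolerance = 1e-6)
  expect_equal(sr$overlap_value, sr2$overlap_value, tolerance = 1e-9)
})

test_that("the found overlap never beats naive PCA in the wrong direction", {
  # the search result must be at least as separating as the first combined
  # PCA eigenvector
  gg <- gen_two_gaussian_ensembles(dim = 10, n_frames = 800, gap = 4,
                                   covariance = c(9, rep(1, 9)), seed = 10)
  sr <- search_separation_rc(gg$ens1, gg$ens2, d = 5, n_scans = 6,
                             n_vectors = 100, seed = 11)
  v1 <- sr$basis$eigenvectors[, 1]
  o_pca <- overlap(as.vector(gg$ens1$X %*% v1), as.vector(gg$ens2$X %*% v1))
  expect_lte(sr$overlap_value, o_pca + 1e-9)
})

test_that("overlap is invariant under sign flip and rigid shifts of both ensembles", {
  set.seed(12)
  p1 <- matrix(rnorm(300 * 4), 300, 4); p1[, 2] <- p1[, 2] + 3
  p2 <- matrix(rnorm(300 * 4), 300, 4)
  n <- c(0.2, 0.9, -0.1, 0.3); n <- n / sqrt(sum(n^2))
  o <- overlap(as.vector(p1 %*% n), as.vector(p2 %*% n))
  o_neg <- overlap(as.vector(p1 %*% -n), as.vector(p2 %*% -n))
  expect_equal(o, o_neg, tolerance = 1e-12)
  shift <- rnorm(4)
  o_shift <- overlap(as.vector(sweep(p1, 2, shift, `+`) %*% n),
                     as.vector(sweep(p2, 2, shift, `+`) %*% n))
  expect_equal(o, o_shift, tolerance = 1e-9)
})

test_that("recovery error decreases with the planted gap", {
  errs <- sapply(c(2, 4, 8), function(gap) {
    mean(sapply(1:5, function(s) {
      gg <- gen_two_gaussian_ensembles(dim = 8, n_frames = 400, gap = gap,
                                       seed = 100 + s)
      sr <- search_separation_rc(gg$ens1, gg$ens2, d = 4, n_scans = 4,
                                 n_vectors = 80, seed = 200 + s)
      abs(1 - abs(sum(sr$n_hat * gg$separation_vector)))
    }))
  })
  expect_true(all(diff(errs) <= 0))
})

test_that("sweep_d plateaus immediately for a one-axis separation", {
  gg <- gen_two_gaussian_ensembles(dim = 12, n_frames = 500, gap = 8, seed = 13)
  sw <- sweep_d(gg$ens1, gg$ens2, d_values = c(2, 3, 4), n_scans = 4,
                n_vectors = 80, seed = 14)
  expect_true(all(sw$similarity[-1] >= 0 & sw$similarity[-1] <= 1 + 1e-12))
  expect_equal(attr(sw, "d_converged"), 3)  # first d compared to a predecessor
  # overlap roughly non-increasing in d (stochastic tolerance)
  expect_true(all(diff(sw$overlap) <= 0.05))
  expect_error(sweep_d(gg$ens1, gg$ens2, d_values = c(4, 2)), "increasing")
})
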