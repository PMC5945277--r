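test_that("Boltzmann inversion of a Gaussian recovers the quadratic potential", {
  set.seed(30)
  z <- rnorm(1e6)
  pr <- pmf_from_projection(z, bins = list(seq(-4, 4, by = 0.1)))
  sel <- pr$occupied & abs(pr$axis) <= 2
  expect_lt(max(abs(pr$G[sel] - pr$axis[sel]^2 / 2)), 0.05)
  # doubling counts changes nothing (normalization)
  pr2 <- pmf_from_projection(c(z, z), bins = list(seq(-4, 4, by = 0.1)))
  expect_equal(pr2$G[sel], pr$G[sel], tolerance = 1e-12)
  # single occupied bin
  pr3 <- pmf_from_projection(rep(0.5, 100), bins = 10)
  expect_equal(sum(pr3$occupied), 1L)
  expect_equal(pr3$G[pr3$occupied], 0)
  expect_error(pmf_from_projection(numeric(0)), "empty")
})

test_that("2-D PMFs mark empty bins unoccupied rather than zero", {
  set.seed(31)
  Z <- cbind(c(rnorm(2000, -2), rnorm(2000, 2)), rnorm(4000))
  pr <- pmf_from_projection(Z, bins = 25)
  expect_true(is.matrix(pr$G))
  expect_true(any(!pr$occupied))
  expect_true(all(is.na(pr$G[!pr$occupied])))
  expect_equal(min(pr$G[pr$occupied]), 0)
})

test_that("harmonic bias energy follows the textbook formula", {
  w <- umbrella_window(center = 1, spring_k = 100, series = rnorm(200, 1, 0.1))
  expect_equal(bias_energy(1, w), 0)
  expect_equal(bias_energy(1.1, w), 0.5, tolerance = 1e-12)
  expect_equal(bias_energy(0.9, w), bias_energy(1.1, w))
  expect_error(umbrella_window(0, -5, rnorm(10)), "positive")
  expect_error(umbrella_window(0, 5, rnorm(10), discard = 10), "discard")
})

test_that("WHAM on a single unbiased window reduces to direct Boltzmann inversion", {
  set.seed(32)
  z <- rnorm(20000, 0, 0.7)
  w <- umbrella_window(0, 0, z, zero_bias = TRUE)
  brk <- seq(min(z), max(z), length.out = 51)
  pr_wham <- wham(list(w), bins = brk)
  pr_direct <- pmf_from_projection(z, bins = list(brk))
  occ <- pr_wham$occupied & pr_direct$occupied
  expect_lt(max(abs(pr_wham$G[occ] - pr_direct$G[occ])), 1e-10)
})

test_that("WHAM recovers a flat potential within sampling noise", {
  set.seed(33)
  z <- runif(1e5, -1, 1)   # exact sampling of the flat-potential ensemble
  w <- umbrella_window(0, 0, z, zero_bias = TRUE)
  pr <- wham(list(w), bins = 25)
  expect_lt(max(abs(pr$G[pr$occupied & abs(pr$axis) < 0.95])), 0.2)
})

test_that("WHAM reconstructs analytic potentials from umbrella windows", {
  # harmonic, stiffness 1 kT/nm^2 (2.494 kJ/mol/nm^2 at 300 K)
  pot <- toy_potential("harmonic", stiffness = 1)
  wins <- gen_umbrella_windows(pot, centers = seq(-3, 3, by = 1),
                               spring_k = 50, n_steps = 50000,
                               discard = 2000, seed = 34)
  pr <- wham(wins, bins = 60)
  an <- analytic_pmf(pot, bins = pr$axis)
  occ <- pr$occupied & abs(pr$axis) <= 2.5
  expect_lt(sqrt(mean((pr$G[occ] - an$G[occ])^2)), 0.2)

  # quartic double well: barrier height within 0.3 kT of the planted 5 kT
  pot2 <- toy_potential("quartic_double_well", barrier_h = 5, width_w = 1)
  wins2 <- gen_umbrella_windows(pot2, centers = seq(-1.6, 1.6, length.out = 11),
                                spring_k = 100, n_steps = 30000,
                                discard = 1000, seed = 35)
  pr2 <- wham(wins2, bins = 80)
  ba <- basin_analysis(pr2)
  barrier <- kink_energy(pr2, ba$barrier_position) -
    mean(c(0, 0))  # barrier above the global minimum
  expect_equal(kink_energy(pr2, 0), 5, tolerance = 0.3)
  expect_equal(abs(ba$ddg), 0, tolerance = 0.4)  # symmetric well
})

test_that("WHAM is gauge-invariant and insensitive to window order", {
  pot <- toy_potential("harmonic", stiffness = 1)
  wins <- gen_umbrella_windows(pot, centers = seq(-2, 2, by = 1),
                               spring_k = 50, n_steps = 8000,
                               discard = 500, seed = 36)
  brk <- seq(-2.6, 2.6, length.out = 51)
  pr <- wham(wins, bins = brk, tol = 1e-11)
  # adding a constant to one window's bias energies changes nothing
  wins_off <- wins
  wins_off[[2]]$offset <- 37.5
  pr_off <- wham(wins_off, bins = brk, tol = 1e-11)
  occ <- pr$occupied
  expect_lt(max(abs(pr$G[occ] - pr_off$G[occ])), 1e-5)
  pr_rev <- wham(rev(wins), bins = brk, tol = 1e-11)
  expect_equal(pr_rev$G[occ], pr$G[occ], tolerance = 1e-8)
  # disconnected ladders are flagged
  far <- gen_umbrella_windows(pot, centers = c(-8, 8), spring_k = 500,
                              n_steps = 2000, discard = 100, seed = 37)
  expect_warning(wham(far, bins = 40), "share no occupied bin")
})

test_that("autocorrelation times follow i.i.d. and AR(1) closed forms", {
  set.seed(38)
  expect_equal(autocorr_time(rnorm(20000)), 0.5, tolerance = 0.1)
  phi <- 0.9
  ar <- as.vector(stats::arima.sim(list(ar = phi), 100000))
  expect_equal(autocorr_time(ar), 0.5 + phi / (1 - phi), tolerance = 0.15 * 9.5)
  s <- rnorm(500)
  expect_equal(autocorr_time(s + 100), autocorr_time(s), tolerance = 1e-10)
  expect_error(autocorr_time(rep(1, 500)), "constant")
  expect_error(autocorr_time(rnorm(50)), "100")
})

test_that("block size arithmetic matches the effective-sample formula", {
  expect_equal(block_size(10000, 4.5), 1000)
  expect_equal(block_size(500, 0), 500)
  taus <- c(0, 1, 2, 5, 10)
  expect_true(all(diff(sapply(taus, function(t) block_size(1e4, t))) < 0))
  expect_equal(block_size(3, 10), 1)  # floored
})

test_that("bootstrap errors behave like sampling geometry demands", {
  pot <- toy_potential("quartic_double_well", barrier_h = 5, width_w = 1)
  wins <- gen_umbrella_windows(pot, centers = seq(-1.6, 1.6, length.out = 11),
                               spring_k = 100, n_steps = 6000,
                               discard = 500, seed = 40)
  # degenerate weights: zero spread by construction
  b0 <- bootstrap_profile_error(wins, bins = 50, n_boot = 4,
                                degenerate_weights = TRUE)
  expect_equal(max(b0$err[b0$occupied]), 0)
  bp <- bootstrap_profile_error(wins, bins = 50, n_boot = 40, seed = 41)
  i_bar <- which.min(abs(bp$axis))
  # replica min-alignment anchors the global minimum, so the barrier must
  # carry more uncertainty than the deepest basin
  i_min <- which.min(bp$G)
  expect_gt(bp$err[i_bar], bp$err[i_min])
  # quadrupling the sampling shrinks the mean error (2 seeds, averaged)
  mean_err <- function(n_steps, seed) {
    ws <- gen_umbrella_windows(pot, centers = seq(-1.6, 1.6, length.out = 11),
                               spring_k = 100, n_steps = n_steps,
                               discard = 500, seed = seed)
    b <- bootstrap_profile_error(ws, bins = 50, n_boot = 25, seed = seed)
    mean(b$err[b$occupied], na.rm = TRUE)
  }
  small <- mean(c(mean_err(3000, 42), mean_err(3000, 43)))
  big <- mean(c(mean_err(12000, 42), mean_err(12000, 43)))
  expect_lt(big, small)
})

test_that("block-average mean-force errors match closed forms", {
  # i.i.d. windows: block SE within 20% of sigma/sqrt(T), averaged over seeds
  ses <- sapply(1:5, function(s) {
    set.seed(50 + s)
    w <- umbrella_window(0, 100, rnorm(10000, 0, 0.2), tau = 0)
    mean_force_error(list(w))$se_mean_z
  })
  expect_equal(mean(ses), 0.2 / sqrt(10000), tolerance = 0.2)
  # correlated series inflate the error beyond the naive estimate
  set.seed(51)
  ar <- as.vector(stats::arima.sim(list(ar = 0.9), 20000)) * 0.05
  w_ar <- umbrella_window(0, 100, ar)
  naive <- stats::sd(ar) / sqrt(length(ar))
  expect_gt(mean_force_error(list(w_ar))$se_mean_z, naive)
  # identical windows get identical errors
  set.seed(52)
  z <- rnorm(5000, 0, 0.1)
  mf <- mean_force_error(list(umbrella_window(-0.1, 80, z, tau = 0),
                              umbrella_window(0.1, 80, z, tau = 0)))
  expect_equal(mf$se_mean_z[1], mf$se_mean_z[2])
  expect_length(attr(mf, "profile_err"), 2L)
  expect_error(mean_force_error(list(umbrella_window(0, 80, 1.0, tau = 0))),
               "blocks")
})

test_that("basin analysis reads depths, ddG and populations off a profile", {
  # piecewise-analytic asymmetric double well with known depth difference
  ax <- seq(-2, 2, length.out = 201)
  G <- ifelse(ax < 0, 8 * (ax + 1)^2, 3 + 5 * (ax - 1)^2)
  G <- pmin(G, 8)  # barrier plateau at 8 kT between the wells
  # planted depths: -8 and -5 kT relative to the barrier, difference 3 kT
  pr <- free_energy_profile(ax, G - min(G))
  ba <- basin_analysis(pr)
  expect_equal(ba$ddg, ba$dg_basin_1 - ba$dg_basin_2)
  expect_equal(abs(ba$ddg), 3, tolerance = 0.3)
  expect_gt(ba$p_deeper, 0.5)
  # mirrored profile flips the sign of ddg
  pr_m <- free_energy_profile(ax, rev(G) - min(G))
  expect_equal(basin_analysis(pr_m)$ddg, -ba$ddg, tolerance = 1e-9)
  # symmetric well: equal depths
  Gs <- 5 * ((ax / 1)^2 - 1)^2
  bas <- basin_analysis(free_energy_profile(ax, Gs))
  expect_equal(bas$ddg, 0, tolerance = 1e-9)
  expect_equal(bas$dg_basin_1, bas$dg_basin_2)
  # single basin: no barrier to divide at
  expect_error(basin_analysis(free_energy_profile(ax, ax^2)), "barrier|minima")
})

test_that("two-state populations follow the Boltzmann closed form", {
  expect_equal(round(100 * population_fraction(8.6), 2), 99.98)
  expect_equal(population_fraction(0), 0.5)
  expect_equal(population_fraction(1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(population_fraction(-1), population_fraction(1))
  # the two basins' populations are complementary
  ddg <- 2.3
  p <- population_fraction(ddg)
  expect_equal(p + (1 - p), 1)
  expect_error(population_fraction(Inf), "finite")
})

test_that("kink energies are profile lookups relative to the minimum", {
  pot <- toy_potential("harmonic", stiffness = 1)
  pr <- analytic_pmf(pot, bins = seq(-3, 3, by = 0.05))
  expect_equal(kink_energy(pr, 0), 0)
  expect_equal(kink_energy(pr, 2), 2.0, tolerance = 0.2)  # z = 2 sigma-equivalent
  expect_error(kink_energy(pr, 10), "outside")
})

test_that("bond-energy budgets are plain commutative sums", {
  expect_equal(bond_energy_budget(-16.8, -3.6), -20.4)
  expect_equal(bond_energy_budget(0, 0), 0)
  expect_equal(bond_energy_budget(-3.6, -16.8), bond_energy_budget(-16.8, -3.6))
})

test_that("profiles round-trip through delimited text", {
  pr <- analytic_pmf(toy_potential("quartic_double_well"), bins = 40)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(pr, path)
  back <- read_profile(path)
  expect_equal(back$G, pr$G, tolerance = 1e-9)
})
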