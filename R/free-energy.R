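#' Umbrella window container
#'
#' Bundles one umbrella-sampling window: the harmonic bias position and
#' spring constant, the time-ordered reaction-coordinate series, the
#' initial equilibration span to discard, and (optionally) the integrated
#' autocorrelation time.
#'
#' @param center bias position along the reaction coordinate (nm).
#' @param spring_k harmonic spring constant (kJ mol^-1 nm^-2); must be > 0
#'   unless `zero_bias = TRUE`.
#' @param series numeric vector of reaction-coordinate samples z(t) (nm).
#' @param discard number of initial samples dropped as equilibration
#'   (default 0).
#' @param tau integrated autocorrelation time in samples, in the convention
#'   where the effective sample size is T/(2 tau + 1) (optional).
#' @param zero_bias if `TRUE` the window is unbiased (spring_k treated as
#'   0), the flat-bias limit used for plain Boltzmann inversion.
#' @param offset constant added to the bias energy (kJ/mol, default 0); a
#'   gauge choice that must not change the reconstructed profile.
#' @return an object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, spring_k, series, discard = 0L,
                            tau = NULL, zero_bias = FALSE, offset = 0) {
  if (!zero_bias && spring_k <= 0)
    stop_input("spring_k must be positive (or set zero_bias = TRUE)")
  if (discard >= length(series))
    stop_input("discard span covers the whole series")
  structure(list(center = center,
                 spring_k = if (zero_bias) 0 else spring_k,
                 series = as.numeric(series), discard = as.integer(discard),
                 tau = tau, zero_bias = zero_bias, offset = offset),
            class = "umbrella_window")
}

window_samples <- function(w) {
  if (w$discard > 0) w$series[-seq_len(w$discard)] else w$series
}

#' Harmonic bias energy of an umbrella window
#'
#' V(z) = 1/2 k (z - center)^2.
#'
#' @param z reaction-coordinate value(s) (nm).
#' @param window an [umbrella_window].
#' @return bias energy in kJ/mol (vectorized over `z`).
#' @export
bias_energy <- function(z, window) {
  0.5 * window$spring_k * (z - window$center)^2 + (window$offset %||% 0)
}

#' Free-energy profile from unbiased projections
#'
#' Boltzmann inversion of a normalized histogram: G = -ln(rho / rho_max) in
#' kT. Supports one or two coordinates (a 2-D free-energy surface over the
#' separation coordinate and an orthogonal bending coordinate). Empty bins
#' are marked unoccupied (NA), not zero.
#'
#' @param proj a `projection`, a numeric vector (1-D), or a 2-column matrix
#'   (2-D).
#' @param bins number of bins per axis (default 100) or a list of explicit
#'   break vectors.
#' @return an object of class `free_energy_profile`: `axis` (bin centers;
#'   list of two for 2-D), `G` (kT, minimum 0; vector or matrix),
#'   `err` (zeros; error estimators fill it), `occupied` (logical mask).
#' @export
pmf_from_projection <- function(proj, bins = 100) {
  Z <- if (inherits(proj, "projection")) proj$coords else proj
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = 1)
  if (nrow(Z) == 0) stop_input("empty projection")
  nd <- ncol(Z)
  if (!nd %in% c(1, 2)) stop_input("pmf supports 1 or 2 coordinates")
  brk <- make_breaks(Z, bins)
  if (nd == 1) {
    z <- Z[, 1]
    z <- z[z >= brk[[1]][1] & z <= brk[[1]][length(brk[[1]])]]
    if (length(z) == 0) stop_input("no samples fall inside the bin range")
    counts <- graphics::hist(z, breaks = brk[[1]], plot = FALSE)$counts
    G_from_counts(counts, mids(brk[[1]]))
  } else {
    i <- findInterval(Z[, 1], brk[[1]], rightmost.closed = TRUE,
                      all.inside = TRUE)
    j <- findInterval(Z[, 2], brk[[2]], rightmost.closed = TRUE,
                      all.inside = TRUE)
    counts <- matrix(0, length(brk[[1]]) - 1, length(brk[[2]]) - 1)
    for (k in seq_len(nrow(Z))) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1
    G_from_counts(counts, list(mids(brk[[1]]), mids(brk[[2]])))
  }
}

mids <- function(br) (br[-1] + br[-length(br)]) / 2

make_breaks <- function(Z, bins) {
  if (is.list(bins)) return(bins)
  lapply(seq_len(ncol(Z)), function(k) {
    r <- range(Z[, k])
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  })
}

G_from_counts <- function(counts, axis) {
  occupied <- counts > 0
  G <- ifelse(occupied, -log(counts / max(counts)), NA_real_)
  free_energy_profile(axis, G, err = ifelse(occupied, 0, NA_real_))
}

#' Construct a free-energy profile object
#'
#' @param axis bin centers (nm); a list of two vectors for a 2-D surface.
#' @param G free energies per bin (kT); NA marks unoccupied bins. The
#'   occupied minimum is aligned to 0.
#' @param err per-bin standard errors (kT), optional.
#' @return an object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(axis, G, err = NULL) {
  occupied <- is.finite(G)
  if (!any(occupied)) stop_input("profile has no occupied bins")
  G <- G - min(G[occupied])
  if (is.null(err)) err <- ifelse(occupied, 0, NA_real_)
  structure(list(axis = axis, G = G, err = err, occupied = occupied),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  nd <- if (is.list(x$axis)) 2 else 1
  cat(sprintf("free_energy_profile: %d-D, %d occupied bins, max G = %.2f kT\n",
              nd, sum(x$occupied), max(x$G[x$occupied])))
  invisible(x)
}

#' WHAM reconstruction of a free-energy profile from umbrella windows
#'
#' Standard weighted-histogram self-consistent iteration: with per-window
#' histograms n_i(b), (effective) sample counts N_i and bias energies
#' c_i(b) in kT, the unbiased probability is
#' `P(b) = sum_i n_i(b) / sum_i N_i exp(f_i - c_i(b))`, and the window
#' constants f_i are updated from P until the largest change falls below
#' `tol`. Each window's `discard` span is dropped before histogramming.
#'
#' @param windows list of [umbrella_window]s.
#' @param bins number of bins over the occupied range (default 100) or an
#'   explicit break vector.
#' @param temperature Kelvin (default 300); converts spring constants from
#'   kJ/mol to kT.
#' @param tol convergence tolerance on the window constants (kT, default
#'   1e-7).
#' @param max_iter iteration cap.
#' @param weights optional per-window non-negative weights (used by the
#'   Bayesian bootstrap); default equal.
#' @return a `free_energy_profile` (err is zero; see
#'   [bootstrap_profile_error] and [mean_force_error]).
#' @export
wham <- function(windows, bins = 100, temperature = 300, tol = 1e-7,
                 max_iter = 100000, weights = NULL) {
  if (length(windows) == 0) stop_input("need at least one window")
  kT <- kT_kJmol(temperature)
  samples <- lapply(windows, window_samples)
  all_z <- unlist(samples)
  brk <- if (length(bins) > 1) bins else {
    r <- range(all_z)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  }
  nb <- length(brk) - 1
  centers <- mids(brk)
  W <- length(windows)
  n_ib <- matrix(0, W, nb)
  for (i in seq_len(W)) {
    zi <- samples[[i]]
    zi <- zi[zi >= brk[1] & zi <= brk[length(brk)]]
    n_ib[i, ] <- graphics::hist(zi, breaks = brk, plot = FALSE)$counts
  }
  check_window_overlap(n_ib, windows)
  w <- weights %||% rep(1, W)
  if (length(w) != W || any(w < 0)) stop_input("bad window weights")
  N_i <- rowSums(n_ib) * w
  num <- colSums(n_ib * w)
  # bias energies in kT at bin centers
  c_ib <- t(vapply(windows, function(win) bias_energy(centers, win) / kT,
                   numeric(nb)))
  f_i <- rep(0, W)
  for (it in seq_len(max_iter)) {
    # denominator: sum_i N_i exp(f_i - c_i(b))
    denom <- colSums(N_i * exp(f_i - c_ib))
    P <- ifelse(denom > 0, num / denom, 0)
    f_new <- -log(pmax(rowSums(sweep(exp(-c_ib), 2, P, `*`)), 1e-300))
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f_i)) < tol) { f_i <- f_new; break }
    f_i <- f_new
  }
  denom <- colSums(N_i * exp(f_i - c_ib))
  P <- ifelse(denom > 0 & num > 0, num / denom, NA_real_)
  G <- -log(P / max(P, na.rm = TRUE))
  free_energy_profile(centers, G)
}

check_window_overlap <- function(n_ib, windows) {
  W <- nrow(n_ib)
  if (W < 2) return(invisible())
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  for (k in seq_len(W - 1)) {
    a <- n_ib[ord[k], ] > 0
    b <- n_ib[ord[k + 1], ] > 0
    if (!any(a & b))
      warning(sprintf("adjacent windows at %.3g and %.3g nm share no occupied bin",
                      windows[[ord[k]]]$center, windows[[ord[k + 1]]]$center))
  }
  invisible()
}

#' Integrated autocorrelation time of a scalar series
#'
#' Returns the integrated autocorrelation time
#' `tau_int = 1/2 + sum_{t>=1} rho(t)` with an automatic self-consistent
#' summation window (the sum is cut at the first lag L >= 6 tau_int(L),
#' Sokal's criterion). Under this convention white noise gives tau = 0.5
#' and the effective sample size is T / (2 tau); the block-size formula
#' T/(2 tau' + 1) of [block_size] uses tau' = tau - 1/2.
#'
#' @param series numeric vector, >= 100 samples.
#' @return tau in samples.
#' @export
autocorr_time <- function(series) {
  Tn <- length(series)
  if (Tn < 100) stop_input("need at least 100 samples")
  if (stats::sd(series) == 0) stop_input("constant series has no autocorrelation time")
  ac <- stats::acf(series, lag.max = min(Tn - 1, 10000), plot = FALSE,
                   demean = TRUE)$acf[-1]
  tau <- 0.5
  for (L in seq_along(ac)) {
    tau <- tau + ac[L]
    if (L >= 6 * tau) break
  }
  max(tau, 0.5)
}

#' Optimal block size for block averaging
#'
#' T / (2 tau + 1), floored to at least 1 sample, with tau in the
#' convention where this expression is the effective number of independent
#' samples (tau = 0 for an i.i.d. series).
#'
#' @param T_i series length in samples.
#' @param tau autocorrelation time in samples (>= 0).
#' @return block size in samples.
#' @export
block_size <- function(T_i, tau) {
  if (T_i <= 0) stop_input("T_i must be positive")
  if (tau < 0) stop_input("tau must be >= 0")
  max(floor(T_i / (2 * tau + 1)), 1L)
}

#' Bayesian-bootstrap error of a WHAM profile
#'
#' Repeats the WHAM reconstruction with the complete window histograms
#' reweighted by Dirichlet(1, ..., 1) weights over windows (whole
#' histograms are resampled, not individual samples). Each replica profile
#' is aligned to minimum 0 before the per-bin standard deviation across
#' replicas is taken as the error.
#'
#' @inheritParams wham
#' @param n_boot number of bootstrap replicas (>= 2).
#' @param seed RNG seed.
#' @param degenerate_weights if `TRUE`, every replica uses equal weights
#'   (test hook: the error must then be exactly 0).
#' @return a `free_energy_profile` whose `err` field holds the bootstrap
#'   standard errors.
#' @export
bootstrap_profile_error <- function(windows, bins = 100, temperature = 300,
                                    n_boot = 50, seed = 1, tol = 1e-7,
                                    degenerate_weights = FALSE) {
  if (n_boot < 2) stop_input("n_boot must be >= 2")
  base <- wham(windows, bins = bins, temperature = temperature, tol = tol)
  brk <- profile_breaks(base)
  W <- length(windows)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(base$G))
  for (r in seq_len(n_boot)) {
    wts <- if (degenerate_weights) rep(1, W) else {
      g <- stats::rexp(W)        # Dirichlet(1,...,1) via normalized exponentials
      g / sum(g) * W
    }
    pr <- suppressWarnings(wham(windows, bins = brk, temperature = temperature,
                                tol = tol, weights = wts))
    reps[r, ] <- pr$G
  }
  err <- apply(reps, 2, function(col) {
    if (all(is.finite(col))) stats::sd(col) else NA_real_
  })
  base$err <- err
  base
}

profile_breaks <- function(profile) {
  ax <- profile$axis
  step <- ax[2] - ax[1]
  c(ax - step / 2, ax[length(ax)] + step / 2)
}

#' Block-average mean-force errors per window
#'
#' For each window the standard error of the window-mean reaction
#' coordinate is estimated from block means, with the block size from
#' [block_size] using the window's stored autocorrelation time (computed
#' via [autocorr_time] if absent). The mean-force error of a harmonic
#' window is `spring_k * SE(mean z)`; integrating these across the window
#' ladder (trapezoidal, in quadrature) gives a cumulative profile-level
#' uncertainty, reported as a cross-check alongside the bootstrap error.
#'
#' @param windows list of [umbrella_window]s.
#' @param temperature Kelvin.
#' @return data frame with one row per window: `center`, `se_mean_z` (nm),
#'   `se_force` (kT/nm), `block_size`, `n_blocks`, and attribute
#'   `profile_err` (cumulative kT uncertainty at each window, in ladder
#'   order).
#' @export
mean_force_error <- function(windows, temperature = 300) {
  kT <- kT_kJmol(temperature)
  rows <- lapply(windows, function(w) {
    z <- window_samples(w)
    tau <- w$tau %||% max(autocorr_time(z) - 0.5, 0)
    # the optimal block size, capped so that >= 10 blocks remain (an i.i.d.
    # series would otherwise yield a single block and no spread estimate)
    B <- min(block_size(length(z), tau), max(floor(length(z) / 10), 1))
    nb <- floor(length(z) / B)
    if (nb < 2) stop_input("fewer than 2 blocks at the optimal block size")
    bm <- vapply(seq_len(nb), function(b) mean(z[((b - 1) * B + 1):(b * B)]),
                 numeric(1))
    se_z <- stats::sd(bm) / sqrt(nb)
    data.frame(center = w$center, se_mean_z = se_z,
               se_force = w$spring_k * se_z / kT,
               block_size = B, n_blocks = nb)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$center), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 1) {
    dz <- diff(out$center)
    seg <- (out$se_force[-1] + out$se_force[-nrow(out)]) / 2 * abs(dz)
    attr(out, "profile_err") <- c(0, sqrt(cumsum(seg^2)))
  } else {
    attr(out, "profile_err") <- 0
  }
  out
}

#' Basin depths, free-energy difference and barrier of a double-well profile
#'
#' Locates the two deepest local minima (after a 3-bin moving-average
#' smoothing to suppress histogram noise) and the highest interior maximum
#' between them (the dividing transition state). Basin depths are reported
#' relative to that maximum, i.e. as negative numbers
#' `G(minimum) - G(barrier)`; `ddg` is the depth difference (basin 1 minus
#' basin 2, basins ordered along the axis); `p_deeper` is the two-state
#' Boltzmann population of the deeper basin.
#'
#' @param profile a 1-D `free_energy_profile`.
#' @param split `"auto"` (default) or an explicit reaction-coordinate value
#'   at which to divide the basins.
#' @return an object of class `basin_analysis`: `dg_basin_1`, `dg_basin_2`
#'   (kT, negative), `ddg`, `p_deeper`, `barrier_position` (nm),
#'   `min_positions` (nm).
#' @export
basin_analysis <- function(profile, split = "auto") {
  if (is.list(profile$axis)) stop_input("basin analysis needs a 1-D profile")
  occ <- which(profile$occupied)
  ax <- profile$axis[occ]
  G <- profile$G[occ]
  Gs <- smooth3(G)
  if (identical(split, "auto")) {
    mins <- local_minima(Gs)
    if (length(mins) < 2)
      stop_input("no interior barrier: profile has fewer than 2 local minima")
    two <- mins[order(Gs[mins])][1:2]
    two <- sort(two)
    inner <- (two[1] + 1):(two[2] - 1)
    if (length(inner) == 0) stop_input("no interior barrier between the minima")
    bar <- inner[which.max(Gs[inner])]
  } else {
    bar <- which.min(abs(ax - split))
    two <- c(if (bar > 1) which.min(G[1:(bar - 1)]) else 1,
             bar + which.min(G[(bar + 1):length(G)]))
  }
  # depths from the raw (unsmoothed) profile at the located bins
  left <- which.min(G[1:(bar - 1)])
  right <- bar + which.min(G[(bar + 1):length(G)])
  dg1 <- G[left] - G[bar]
  dg2 <- G[right] - G[bar]
  ddg <- dg1 - dg2
  structure(list(dg_basin_1 = dg1, dg_basin_2 = dg2, ddg = ddg,
                 p_deeper = population_fraction(ddg),
                 barrier_position = ax[bar],
                 min_positions = c(ax[left], ax[right])),
            class = "basin_analysis")
}

#' @export
print.basin_analysis <- function(x, ...) {
  cat(sprintf("basins: dG1 = %.2f kT, dG2 = %.2f kT, ddG = %.2f kT\n",
              x$dg_basin_1, x$dg_basin_2, x$ddg))
  cat(sprintf("barrier at %.3g nm; deeper-basin population %.4f\n",
              x$barrier_position, x$p_deeper))
  invisible(x)
}

smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out
}

local_minima <- function(x) {
  n <- length(x)
  which(vapply(seq_len(n), function(i) {
    (i == 1 || x[i] <= x[i - 1]) && (i == n || x[i] < x[i + 1])
  }, logical(1)))
}

#' Two-state Boltzmann population of the deeper basin
#'
#' p = 1 / (1 + exp(-|ddg|)) for a free-energy difference `ddg` in kT; the
#' population of the deeper of two states.
#'
#' @param ddg basin free-energy difference (kT).
#' @return population fraction in (0.5, 1]; 0.5 when ddg = 0.
#' @export
population_fraction <- function(ddg) {
  if (!is.finite(ddg)) stop_input("ddg must be finite")
  1 / (1 + exp(-abs(ddg)))
}

#' Free-energy cost of holding a structure at a profile position
#'
#' The free energy, relative to the profile minimum, at the reaction
#' coordinate of a reference structure (e.g. the straight lattice
#' conformation on a bending profile) — the kinking free energy stored in
#' a dimer held at that position. Nearest-bin lookup.
#'
#' @param profile a 1-D `free_energy_profile`.
#' @param position reaction-coordinate value (nm).
#' @return free energy in kT (>= 0).
#' @export
kink_energy <- function(profile, position) {
  occ <- which(profile$occupied)
  ax <- profile$axis[occ]
  step <- if (length(profile$axis) > 1)
    profile$axis[2] - profile$axis[1] else 1
  i <- which.min(abs(ax - position))
  if (abs(ax[i] - position) > step)
    stop_input("position ", position, " lies outside the occupied range")
  profile$G[occ][i]
}

#' Combined lateral plus longitudinal bond energy
#'
#' Bookkeeping helper: the energy of forming one lateral and one
#' longitudinal lattice contact, for comparison against basin barriers.
#'
#' @param longitudinal,lateral bond energies (kT, negative for favorable).
#' @return their sum (kT).
#' @export
bond_energy_budget <- function(longitudinal, lateral) {
  longitudinal + lateral
}

#' Write / read a 1-D free-energy profile as delimited text
#'
#' Columns: bin center (nm), G (kT), err (kT).
#'
#' @param profile a 1-D `free_energy_profile`.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(center = profile$axis, G = profile$G, err = profile$err)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  free_energy_profile(df$center, df$G, df$err)
}
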