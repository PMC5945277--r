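#' Fit a 1-D projected density model
#'
#' The gaussian model summarizes projected samples by their mean and
#' population standard deviation (division by the sample count); the
#' histogram model returns normalized bin densities on a Freedman-Diaconis
#' grid. Both integrate to 1.
#'
#' @param z numeric vector of projected reaction-coordinate values.
#' @param model `"gaussian"` or `"histogram"`.
#' @param breaks optional histogram break points (shared-grid overlap needs
#'   a common grid).
#' @return for `"gaussian"`, a list `(model, mu, sigma)`; for
#'   `"histogram"`, a list `(model, breaks, density)`.
#' @export
projected_density <- function(z, model = c("gaussian", "histogram"),
                              breaks = NULL) {
  model <- match.arg(model)
  if (model == "gaussian") {
    if (length(z) < 2) stop_input("gaussian density needs >= 2 samples")
    mu <- mean(z)
    sigma <- sqrt(mean((z - mu)^2))
    if (sigma <= 0) stop_input("degenerate (zero-variance) projection")
    list(model = "gaussian", mu = mu, sigma = sigma)
  } else {
    if (is.null(breaks)) breaks <- fd_breaks(z)
    h <- graphics::hist(z, breaks = breaks, plot = FALSE)
    list(model = "histogram", breaks = h$breaks, density = h$density)
  }
}

# Freedman-Diaconis break points padded by 3 bin widths beyond the range.
fd_breaks <- function(z, pad_bins = 3) {
  bw <- 2 * stats::IQR(z) / length(z)^(1 / 3)
  if (bw <= 0) bw <- max(diff(range(z)) / 30, 1e-8)
  lo <- min(z) - pad_bins * bw
  hi <- max(z) + pad_bins * bw
  seq(lo, hi, length.out = max(ceiling((hi - lo) / bw), 2) + 1)
}

#' Overlap integral of two projected densities
#'
#' Computes O = integral of rho1(z) * rho2(z) dz. Under the gaussian model
#' the closed form
#' `exp(-(mu1-mu2)^2 / (2 (s1^2+s2^2))) / sqrt(2 pi (s1^2+s2^2))`
#' is used; under the histogram model both samples are binned on a shared
#' Freedman-Diaconis grid over the pooled range and the product summed.
#'
#' @param z1,z2 projected samples of the two ensembles.
#' @param model `"gaussian"` or `"histogram"`.
#' @return the overlap (non-negative scalar; two identical standard normal
#'   densities give 1/(2 sqrt(pi)) ~ 0.282).
#' @export
overlap <- function(z1, z2, model = c("gaussian", "histogram")) {
  model <- match.arg(model)
  if (model == "gaussian") {
    d1 <- projected_density(z1, "gaussian")
    d2 <- projected_density(z2, "gaussian")
    s2 <- d1$sigma^2 + d2$sigma^2
    exp(-(d1$mu - d2$mu)^2 / (2 * s2)) / sqrt(2 * pi * s2)
  } else {
    br <- fd_breaks(c(z1, z2))
    d1 <- projected_density(z1, "histogram", breaks = br)
    d2 <- projected_density(z2, "histogram", breaks = br)
    sum(d1$density * d2$density * diff(br))
  }
}

#' Random unit vectors with normally distributed coordinates
#'
#' Coordinates are drawn i.i.d. standard normal and each vector normalized,
#' giving the uniform distribution on the (d-1)-sphere.
#'
#' @param d dimension.
#' @param count number of vectors.
#' @return a `count x d` matrix of unit row vectors.
#' @export
random_unit_vectors <- function(d, count) {
  M <- matrix(stats::rnorm(count * d), count, d)
  M / sqrt(rowSums(M^2))
}

# Overlap along direction v (not necessarily normalized) of two projected
# coordinate sets; the objective minimized by the scans.
overlap_along <- function(v, proj1, proj2, model) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(Inf)
  v <- v / nv
  overlap(as.vector(proj1 %*% v), as.vector(proj2 %*% v), model)
}

#' One scan of the separation search
#'
#' Generates `n_vectors` random unit candidates, keeps the one with minimal
#' projected-density overlap, and refines it by downhill-simplex
#' (Nelder-Mead) minimization of O(n/|n|) over the d coordinates.
#' Normalization happens inside the objective, so the optimizer works on
#' unconstrained vectors.
#'
#' @param proj1,proj2 F1 x d and F2 x d coordinate matrices in the shared
#'   PCA basis.
#' @param n_vectors random candidates for the global stage.
#' @param model density model for the overlap.
#' @param simplex_tol relative convergence tolerance of the simplex stage.
#' @return list with `vector` (unit d-vector) and `overlap`.
#' @export
run_scan <- function(proj1, proj2, n_vectors = 2000,
                     model = "gaussian", simplex_tol = 1e-8) {
  d <- ncol(proj1)
  cand <- random_unit_vectors(d, n_vectors)
  # all candidate overlaps in two matrix products
  Z1 <- proj1 %*% t(cand)
  Z2 <- proj2 %*% t(cand)
  ovs <- vapply(seq_len(n_vectors), function(i) {
    m1 <- mean(Z1[, i]); s1 <- sqrt(mean((Z1[, i] - m1)^2))
    m2 <- mean(Z2[, i]); s2 <- sqrt(mean((Z2[, i] - m2)^2))
    if (model == "gaussian") {
      s2sum <- s1^2 + s2^2
      exp(-(m1 - m2)^2 / (2 * s2sum)) / sqrt(2 * pi * s2sum)
    } else {
      overlap(Z1[, i], Z2[, i], model)
    }
  }, numeric(1))
  best <- cand[which.min(ovs), ]
  opt <- stats::optim(best, overlap_along, proj1 = proj1, proj2 = proj2,
                      model = model, method = "Nelder-Mead",
                      control = list(reltol = simplex_tol, maxit = 500 * d))
  if (opt$convergence != 0)
    warning("simplex did not converge within the iteration cap; returning best-so-far")
  v <- opt$par / sqrt(sum(opt$par^2))
  ov <- min(opt$value, min(ovs))
  if (opt$value > min(ovs)) v <- cand[which.min(ovs), ]
  list(vector = v, overlap = ov)
}

#' Search for the ensemble-separation reaction coordinate
#'
#' Finds the unit vector along which the projected probability densities of
#' two conformational ensembles overlap least. A PCA basis is built on the
#' combined ensemble; both ensembles are expressed in the first `d` modes
#' (d acts as a regularization dimension); `n_scans` independent scans each
#' pick the best of `n_vectors` random unit directions and refine it by
#' downhill simplex; scan vectors are sign-aligned (flipped to positive dot
#' product with the running mean, the first scan defining the orientation)
#' and averaged; the renormalized average is re-embedded into full 3N
#' coordinate space.
#'
#' @param flat1,flat2 [flat_ensemble]s over the same atom set.
#' @param d number of combined-PCA modes spanning the search space.
#' @param n_scans independent scans (publication-scale default 500).
#' @param n_vectors random candidates per scan (default 2000).
#' @param model density model (`"gaussian"` default; `"histogram"` as a
#'   cross-check).
#' @param seed RNG seed for the random candidate streams.
#' @param simplex_tol simplex convergence tolerance.
#' @return an object of class `separation_result`: `n_hat` (unit 3N
#'   vector), `n_hat_d` (in the d-mode basis), `overlap_value`,
#'   `scan_vectors` (n_scans x d, sign-aligned), `variance_trace`
#'   (n_scans x d running per-coordinate variances), `basis` (the combined
#'   PCA basis), `d_used`.
#' @export
search_separation_rc <- function(flat1, flat2, d = 10, n_scans = 500,
                                 n_vectors = 2000, model = "gaussian",
                                 seed = 1, simplex_tol = 1e-8) {
  if (ncol(flat1$X) != ncol(flat2$X))
    stop_input("ensembles must share the same coordinate dimension")
  combined <- flat_ensemble(rbind(flat1$X, flat2$X))
  basis <- compute_pca(combined)
  if (d > ncol(basis$eigenvectors))
    stop_input("d = ", d, " exceeds the ", ncol(basis$eigenvectors),
               " available combined-PCA modes")
  if (d < 2) stop_input("d must be >= 2")
  modes <- seq_len(d)
  proj1 <- project(flat1, basis, modes)$coords
  proj2 <- project(flat2, basis, modes)$coords

  scan_vecs <- matrix(NA_real_, n_scans, d)
  scan_ovs <- numeric(n_scans)
  set.seed(seed)
  scan_seeds <- sample.int(2147483646L, n_scans)
  running_mean <- NULL
  for (s in seq_len(n_scans)) {
    set.seed(scan_seeds[s])
    res <- run_scan(proj1, proj2, n_vectors = n_vectors, model = model,
                    simplex_tol = simplex_tol)
    v <- res$vector
    if (is.null(running_mean)) {
      running_mean <- v
    } else {
      if (sum(v * running_mean) < 0) v <- -v
      running_mean <- ((s - 1) * running_mean + v) / s
    }
    scan_vecs[s, ] <- v
    scan_ovs[s] <- res$overlap
  }
  # running per-coordinate variance of the aligned scan vectors
  variance_trace <- matrix(NA_real_, n_scans, d)
  for (s in seq_len(n_scans))
    variance_trace[s, ] <- if (s == 1) 0 else
      apply(scan_vecs[seq_len(s), , drop = FALSE], 2, stats::var)

  n_d <- colMeans(scan_vecs)
  n_d <- n_d / sqrt(sum(n_d^2))
  ov <- overlap_along(n_d, proj1, proj2, model)
  n_hat <- as.vector(basis$eigenvectors[, modes] %*% n_d)
  n_hat <- n_hat / sqrt(sum(n_hat^2))
  structure(list(n_hat = n_hat, n_hat_d = n_d, overlap_value = ov,
                 scan_vectors = scan_vecs, scan_overlaps = scan_ovs,
                 variance_trace = variance_trace, basis = basis,
                 d_used = d, model = model),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("separation_result: d = %d, overlap = %.4g (%s model, %d scans)\n",
              x$d_used, x$overlap_value, x$model, nrow(x$scan_vectors)))
  invisible(x)
}

#' Scan the regularization dimension d
#'
#' Runs the separation search for each value in `d_values` and reports the
#' overlap plus the cosine similarity between consecutive full-space
#' separation vectors; the smallest d whose similarity with the previous
#' solution exceeds `plateau` is flagged as converged.
#'
#' @param flat1,flat2 [flat_ensemble]s.
#' @param d_values increasing integer vector of basis dimensions.
#' @param plateau cosine-similarity threshold declaring d-independence
#'   (default 0.98).
#' @param ... passed on to [search_separation_rc].
#' @return a data frame with columns `d`, `overlap`, `similarity` (NA for
#'   the first entry) and attribute `d_converged`.
#' @export
sweep_d <- function(flat1, flat2, d_values, plateau = 0.98, ...) {
  if (is.unsorted(d_values, strictly = TRUE))
    stop_input("d_values must be strictly increasing")
  res <- lapply(d_values, function(d)
    search_separation_rc(flat1, flat2, d = d, ...))
  sim <- rep(NA_real_, length(d_values))
  for (i in seq_along(res)[-1])
    sim[i] <- abs(sum(res[[i]]$n_hat * res[[i - 1]]$n_hat))
  out <- data.frame(d = d_values,
                    overlap = vapply(res, `[[`, numeric(1), "overlap_value"),
                    similarity = sim)
  conv <- which(sim >= plateau)
  attr(out, "d_converged") <- if (length(conv)) d_values[min(conv)] else NA
  attr(out, "results") <- res
  out
}
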