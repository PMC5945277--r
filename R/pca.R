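#' Principal component analysis of a flat ensemble
#'
#' Eigendecomposition of the covariance matrix of the mean-centered rows of
#' `flat$X`. The covariance uses the population convention (division by F,
#' the number of frames), since it is defined as an ensemble average.
#' When 3N > F the decomposition is carried out exactly through the F x F
#' Gram matrix, which is what makes structure sets with far more
#' coordinates than frames tractable. Eigenvector signs are fixed so that
#' the largest-magnitude component of each eigenvector is positive;
#' eigenvalues below 1e-12 nm^2 are clipped to zero.
#'
#' @param flat a [flat_ensemble] with at least 2 frames.
#' @return an object of class `pca_basis` with fields `mean` (3N vector),
#'   `eigenvectors` (3N x K matrix, columns orthonormal), `eigenvalues`
#'   (descending, nm^2) and `n_frames`.
#' @export
compute_pca <- function(flat) {
  X <- flat$X
  Fn <- nrow(X)
  if (Fn < 2) stop_input("PCA needs at least 2 frames")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  p <- ncol(X)
  if (p > Fn) {
    # Gram route: XcXc'/F shares nonzero eigenvalues with the covariance
    G <- tcrossprod(Xc) / Fn
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > 1e-12
    lambda <- eg$values[keep]
    V <- crossprod(Xc, eg$vectors[, keep, drop = FALSE])
    V <- sweep(V, 2, sqrt(Fn * lambda), `/`)
  } else {
    C <- crossprod(Xc) / Fn
    eg <- eigen(C, symmetric = TRUE)
    lambda <- pmax(eg$values, 0)
    lambda[lambda < 1e-12] <- 0
    V <- eg$vectors
  }
  # deterministic sign: largest-magnitude component positive
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  structure(list(mean = mu, eigenvectors = V, eigenvalues = lambda,
                 n_frames = Fn),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("pca_basis: %d modes over %d coordinates (%d frames)\n",
              length(x$eigenvalues), length(x$mean), x$n_frames))
  vf <- variance_fractions(x)
  cat(sprintf("  top modes: %s\n",
              paste(sprintf("%.1f%%", 100 * utils::head(vf, 3)), collapse = ", ")))
  invisible(x)
}

#' Project an ensemble onto conformational modes
#'
#' Computes q_k = (x - <x>) . v_k per frame, using the basis mean, so that
#' foreign ensembles (e.g. simulated ensembles projected onto a basis built
#' from experimental structures) are placed consistently in the same mode
#' space.
#'
#' @param flat a [flat_ensemble] whose column count matches the basis.
#' @param basis a `pca_basis` from [compute_pca].
#' @param modes integer vector of mode indices (default first two).
#' @return an object of class `projection`: fields `coords` (F x d matrix,
#'   nm), `mode_indices` and `frame_labels`.
#' @export
project <- function(flat, basis, modes = c(1L, 2L)) {
  if (ncol(flat$X) != length(basis$mean))
    stop_input("ensemble dimension (", ncol(flat$X),
               ") does not match basis dimension (", length(basis$mean), ")")
  if (any(modes > ncol(basis$eigenvectors)))
    stop_input("requested mode exceeds available modes")
  Xc <- sweep(flat$X, 2, basis$mean)
  Q <- Xc %*% basis$eigenvectors[, modes, drop = FALSE]
  structure(list(coords = Q, mode_indices = as.integer(modes),
                 frame_labels = flat$frame_labels),
            class = "projection")
}

#' Fraction of total variance per conformational mode
#'
#' @param basis a `pca_basis`.
#' @return numeric vector lambda_k / sum(lambda), summing to 1.
#' @export
variance_fractions <- function(basis) {
  tot <- sum(basis$eigenvalues)
  if (tot <= 0) stop_input("degenerate ensemble: all eigenvalues are zero")
  basis$eigenvalues / tot
}

#' Interpolate structures along a conformational mode
#'
#' Builds frames `<x> + a * v_mode` for each requested amplitude, e.g. to
#' render the extreme conformations along the dominant bending mode.
#'
#' @param basis a `pca_basis`.
#' @param mode mode index.
#' @param amplitudes numeric amplitudes in nm.
#' @return a [structure_ensemble] with one frame per amplitude.
#' @export
interpolate_mode <- function(basis, mode, amplitudes) {
  if (any(!is.finite(amplitudes))) stop_input("amplitudes must be finite")
  v <- basis$eigenvectors[, mode]
  X <- t(vapply(amplitudes, function(a) basis$mean + a * v,
                numeric(length(basis$mean))))
  structure_ensemble(X, frame_labels = sprintf("a=%g", amplitudes))
}

#' First principal axis orthogonal to a given direction
#'
#' Removes the component along the unit vector `n` from every centered
#' frame and returns the leading principal axis of the residual — the
#' largest-variance direction orthogonal to `n`, used as the second axis of
#' 2-D free-energy planes (separation coordinate x largest orthogonal
#' motion).
#'
#' @param flat a [flat_ensemble].
#' @param n unit 3N vector.
#' @return unit 3N vector orthogonal to `n`.
#' @export
max_variance_orthogonal <- function(flat, n) {
  n <- n / sqrt(sum(n^2))
  Xc <- sweep(flat$X, 2, colMeans(flat$X))
  Xp <- Xc - (Xc %*% n) %*% t(n)
  b <- compute_pca(flat_ensemble(Xp))
  if (b$eigenvalues[1] < 1e-12)
    warning("residual variance orthogonal to n is degenerate")
  v <- b$eigenvectors[, 1]
  v <- v - sum(v * n) * n
  v / sqrt(sum(v^2))
}

#' Write a 2-D projection as delimited text
#'
#' @param proj a `projection`.
#' @param path file path.
#' @export
write_projection <- function(proj, path) {
  df <- data.frame(frame = proj$frame_labels, proj$coords)
  colnames(df) <- c("frame", paste0("mode", proj$mode_indices))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
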