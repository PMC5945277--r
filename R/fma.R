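#' Per-frame RMSD to a reference conformation
#'
#' Computes the RMSD of every (already superposed) frame of a flat ensemble
#' to a reference 3N vector, without refitting. This is the scalar
#' functional quantity regressed by the functional mode analysis — any
#' deviation from the reference increases it, irrespective of direction.
#'
#' @param flat a [flat_ensemble].
#' @param reference 3N numeric vector (nm).
#' @return numeric vector of per-frame RMSD values (nm).
#' @export
rmsd_series <- function(flat, reference) {
  if (ncol(flat$X) != length(reference))
    stop_input("reference dimension does not match the ensemble")
  n_at <- length(reference) / 3
  D <- sweep(flat$X, 2, reference)
  sqrt(rowSums(D^2) / n_at)
}

# PLS1 (NIPALS with deflation), X and f already centered.
# Returns weights W, loadings P, response loadings q and the implied
# regression coefficients beta in original coordinate space.
pls1_nipals <- function(Xc, fc, k) {
  p <- ncol(Xc)
  W <- matrix(0, p, k); P <- matrix(0, p, k); qv <- numeric(k)
  Xd <- Xc; fd <- fc
  for (a in seq_len(k)) {
    w <- crossprod(Xd, fd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { k <- a - 1L; break }
    w <- w / nw
    t_sc <- Xd %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-300) { k <- a - 1L; break }
    p_ld <- crossprod(Xd, t_sc) / tt
    q_ld <- sum(fd * t_sc) / tt
    Xd <- Xd - t_sc %*% t(p_ld)
    fd <- fd - q_ld * t_sc
    W[, a] <- w; P[, a] <- p_ld; qv[a] <- q_ld
  }
  if (k == 0) stop_input("degenerate target: no PLS component could be extracted")
  W <- W[, seq_len(k), drop = FALSE]
  P <- P[, seq_len(k), drop = FALSE]
  qv <- qv[seq_len(k)]
  beta <- W %*% solve(crossprod(P, W), qv)
  list(W = W, P = P, q = qv, beta = as.vector(beta), k = k)
}

#' Fit a partial-least-squares functional mode model
#'
#' Solves the regression f = X^T W_k beta_k + eps by single-response PLS
#' (NIPALS with deflation): the k basis vectors are built iteratively to
#' capture both variance in X and linear correlation between f and X. At
#' full rank the fitted predictions coincide with ordinary least squares.
#' The ensemble-weighted mode is the normalized coefficient vector of the
#' fitted linear map from centered coordinates to predictions — the
#' collective direction whose motion correlates best with f.
#'
#' @param X F x 3N coordinate matrix (rows = frames), or a
#'   [flat_ensemble].
#' @param f numeric vector of the functional quantity, length F.
#' @param k number of PLS components (1 <= k < F).
#' @return an object of class `fma_model` with fields `basis_W`,
#'   `coeffs_beta` (regression coefficients in coordinate space), `k`,
#'   `mean_x`, `mean_f`, `mode` (unit 3N vector), `fitted`, `rm`
#'   (model-building Pearson correlation).
#' @export
fit_pls <- function(X, f, k) {
  if (inherits(X, "flat_ensemble")) X <- X$X
  Fn <- nrow(X)
  if (k >= Fn) stop_input("k must be smaller than the number of frames")
  if (k < 1) stop_input("k must be >= 1")
  if (stats::sd(f) == 0) stop_input("degenerate target: f is constant")
  mean_x <- colMeans(X)
  mean_f <- mean(f)
  Xc <- sweep(X, 2, mean_x)
  fc <- f - mean_f
  fit <- pls1_nipals(Xc, fc, k)
  fitted <- as.vector(Xc %*% fit$beta) + mean_f
  rm <- stats::cor(f, fitted)
  mode <- fit$beta / sqrt(sum(fit$beta^2))
  structure(list(basis_W = fit$W, coeffs_beta = fit$beta, k = fit$k,
                 mean_x = mean_x, mean_f = mean_f, mode = mode,
                 fitted = fitted, rm = rm),
            class = "fma_model")
}

#' @export
print.fma_model <- function(x, ...) {
  cat(sprintf("fma_model: k = %d components, Rm = %.4f\n", x$k, x$rm))
  invisible(x)
}

#' Predict the functional quantity for new conformations
#'
#' @param object an `fma_model`.
#' @param newdata F x 3N matrix or [flat_ensemble].
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.fma_model <- function(object, newdata, ...) {
  if (inherits(newdata, "flat_ensemble")) newdata <- newdata$X
  Xc <- sweep(newdata, 2, object$mean_x)
  as.vector(Xc %*% object$coeffs_beta) + object$mean_f
}

#' Choose the PLS component count by cross-validation
#'
#' Fits models with k = 1..k_max on the model-building part and evaluates
#' the Pearson correlation Rv between observed and predicted f on the
#' validation part. The default split follows frame order (first half
#' builds, second half validates), matching the usual use of trajectory
#' half-ensembles; a seeded random split is available. The chosen k is the
#' smallest one within `tol` of the maximal Rv (parsimony rule).
#'
#' @param X F x 3N matrix or [flat_ensemble].
#' @param f functional quantity, length F.
#' @param k_max maximal component count to consider.
#' @param split `"half"` (frame-ordered halves) or `"random"`.
#' @param tol parsimony tolerance on Rv (default 0.005).
#' @param seed seed for the random split.
#' @return list with `rv_by_k`, `rm_by_k`, `k` (chosen), `split_index`
#'   (logical, TRUE = model building).
#' @export
cross_validate <- function(X, f, k_max, split = c("half", "random"),
                           tol = 0.005, seed = 1) {
  if (inherits(X, "flat_ensemble")) X <- X$X
  split <- match.arg(split)
  Fn <- nrow(X)
  build <- if (split == "half") {
    seq_len(Fn) <= Fn %/% 2
  } else {
    set.seed(seed)
    idx <- sample.int(Fn, Fn %/% 2)
    seq_len(Fn) %in% idx
  }
  if (sum(build) < 2 || sum(!build) < 2)
    stop_input("split leaves fewer than 2 frames on one side")
  if (stats::sd(f[!build]) == 0)
    stop_input("degenerate split: validation f is constant")
  k_max <- min(k_max, sum(build) - 1L)
  rv <- rm <- numeric(k_max)
  for (k in seq_len(k_max)) {
    m <- fit_pls(X[build, , drop = FALSE], f[build], k)
    rm[k] <- m$rm
    rv[k] <- stats::cor(f[!build], predict(m, X[!build, , drop = FALSE]))
  }
  if (any(!is.finite(rv))) stop_input("non-finite cross-validation correlation")
  k_best <- min(which(rv >= max(rv) - tol))
  list(rv_by_k = rv, rm_by_k = rm, k = k_best, split_index = build)
}

#' Correlation of a fitted model on an independent ensemble
#'
#' @param model an `fma_model`.
#' @param X2 independent F2 x 3N matrix or [flat_ensemble].
#' @param f2 the functional quantity on the independent ensemble.
#' @return the external validation Pearson correlation Rv.
#' @export
validate_independent <- function(model, X2, f2) {
  if (inherits(X2, "flat_ensemble")) X2 <- X2$X
  if (ncol(X2) != length(model$mean_x))
    stop_input("dimension mismatch with the fitted model")
  if (stats::sd(f2) == 0) stop_input("degenerate target: f2 is constant")
  stats::cor(f2, predict(model, X2))
}

#' Full FMA workflow: cross-validated component choice plus final model
#'
#' Convenience wrapper: runs [cross_validate], refits at the chosen k on
#' the model-building part, and reports Rm, Rv and the ensemble-weighted
#' mode.
#'
#' @inheritParams cross_validate
#' @return an `fma_model` with extra fields `rv_by_k`, `rm_by_k`,
#'   `rv` (validation correlation at the chosen k) and `k`.
#' @export
run_fma <- function(X, f, k_max = 20, split = "half", tol = 0.005, seed = 1) {
  if (inherits(X, "flat_ensemble")) X <- X$X
  cv <- cross_validate(X, f, k_max, split = split, tol = tol, seed = seed)
  build <- cv$split_index
  model <- fit_pls(X[build, , drop = FALSE], f[build], cv$k)
  model$rv_by_k <- cv$rv_by_k
  model$rm_by_k <- cv$rm_by_k
  model$rv <- cv$rv_by_k[cv$k]
  model
}
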