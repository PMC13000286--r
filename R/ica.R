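# Symmetric fixed-point FastICA (logcosh contrast) with seeded
# initialization. Operates on a channels x samples matrix; returns the
# unmixing of the whitened data plus everything needed to reconstruct.

fastica_decompose <- function(X, n_comp = nrow(X), max_iter = 200,
                              tol = 1e-5, seed = 42L) {
  stopifnot(ncol(X) > nrow(X))
  ctr <- rowMeans(X)
  Xc <- X - ctr
  covm <- Xc %*% t(Xc) / ncol(Xc)
  eg <- eigen(covm, symmetric = TRUE)
  keep <- seq_len(n_comp)
  d <- eg$values[keep]
  d[d < 1e-12] <- 1e-12
  K <- diag(1 / sqrt(d), n_comp) %*% t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc                        # whitened: cov(Z) = I

  set.seed(seed)
  W <- matrix(rnorm(n_comp * n_comp), n_comp)
  sym_decorrelate <- function(W) {
    s <- W %*% t(W)
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- (G %*% t(Z)) / ncol(Z) - diag(rowMeans(Gp)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  if (it == max_iter && delta > tol) {
    # near-Gaussian sources rotate freely and never settle; the estimate is
    # still usable (scikit-learn convention: warn, do not fail)
    warn(sprintf("FastICA reached %d iterations without full convergence (delta %.2e)",
                 max_iter, delta))
  }
  if (any(!is.finite(W))) {
    abort("FastICA produced a degenerate (non-finite) unmixing matrix.")
  }
  S <- W %*% Z                          # components x samples
  # mixing matrix back to channel space: X ~ A S + ctr
  A <- MASS_ginv(W %*% K)
  list(S = S, A = A, W = W, K = K, center = ctr, n_iter = it)
}

# Small Moore-Penrose pseudo-inverse (avoids depending on MASS for one call).
MASS_ginv <- function(M, tol = 1e-10) {
  sv <- svd(M)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*%
    diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
}

fastica_reconstruct <- function(dec, drop = integer(0)) {
  S <- dec$S
  if (length(drop)) S[drop, ] <- 0
  dec$A %*% S + dec$center
}
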