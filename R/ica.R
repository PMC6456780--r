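# Symmetric FastICA (tanh contrast) on channels-by-samples data. Data are
# centred and whitened by eigendecomposition of the channel covariance;
# rank-deficient inputs keep only components with eigenvalues above
# `tol * max(eigenvalue)`.

fast_ica <- function(X, n_comp = NULL, tol = 1e-8, max_iter = 200,
                     conv_tol = 1e-6, seed = 1L) {
  n_ch <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values)
  if (!is.null(n_comp)) keep <- keep & seq_len(n_ch) <= n_comp
  k <- sum(keep)
  stop_if_not(k >= 1, "ICA: data has rank 0")
  D <- eg$values[keep]
  E <- eg$vectors[, keep, drop = FALSE]
  wh <- diag(1 / sqrt(D), k) %*% t(E)       # whitening: Z = wh %*% Xc
  dewh <- E %*% diag(sqrt(D), k)            # inverse of the whitening map
  Z <- wh %*% Xc

  W <- with_seed(seed, matrix(rnorm(k * k), k, k))
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- tcrossprod(G, Z) / ncol(Z) - gprime * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < conv_tol) break
  }
  S <- W %*% Z                               # sources x samples, unit variance
  A <- dewh %*% t(W)                         # mixing: Xc ~= A %*% S
  list(S = S, A = A, mean = mu, n_comp = k, iterations = it)
}
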