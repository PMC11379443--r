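# Independent brute-force oracles used to validate the package
# implementations. These deliberately use naive loops / textbook formulas and
# share no code with the implementation paths they check.

# naive strided 2-d convolution with zero padding
oracle_conv2d <- function(x, w, b, stride, pad) {
  d <- dim(x); k <- dim(w)[1]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(Cout)) {
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
      acc <- b[co]
      for (ci in seq_len(Cin)) for (j in seq_len(k)) for (i in seq_len(k)) {
        h <- (ho - 1) * stride + i - pad
        ww <- (wo - 1) * stride + j - pad
        if (h >= 1 && h <= d[1] && ww >= 1 && ww <= d[2]) {
          acc <- acc + x[h, ww, ci, n] * w[i, j, ci, co]
        }
      }
      y[ho, wo, co, n] <- acc
    }
  }
  y
}

# per-voxel OLS t statistic via the textbook normal equations
oracle_glm_t <- function(y, X, contrast) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  dof <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / dof
  as.numeric(t(contrast) %*% beta) /
    sqrt(sigma2 * as.numeric(t(contrast) %*% xtx_inv %*% contrast))
}

# counting definition of tolerance accuracy
oracle_tolerance <- function(y_true, y_pred, tol) {
  hits <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == 0) {
      if (y_pred[i] == 0) hits <- hits + 1
    } else if (abs(y_pred[i] - y_true[i]) <= tol * abs(y_true[i])) {
      hits <- hits + 1
    }
  }
  hits / length(y_true)
}

# loop-based mean squared error
oracle_mse <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  s / length(x)
}

# elementwise binary cross-entropy
oracle_bce <- function(p, y) {
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
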