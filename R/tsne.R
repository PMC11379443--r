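# Exact t-distributed stochastic neighbour embedding for visualising latent
# features. The O(n^2) formulation is used (cohort sizes here are a few
# hundred points): Gaussian input affinities with per-point bandwidths
# calibrated to the target perplexity by bisection, Student-t output
# affinities, gradient descent with momentum, adaptive gains and early
# exaggeration.

tsne_affinities <- function(X, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    di <- di - min(di)   # exact shift preventing exp underflow at large beta
    for (iter in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sump <- sum(p)
      H <- log(sump) + beta * sum(di * p) / sump
      diff <- H - logU
      if (!is.finite(diff)) break
      if (abs(diff) < tol) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of latent features
#'
#' @param features matrix (rows = maps) of latent features.
#' @param seed RNG seed for the initial layout.
#' @param perplexity effective neighbourhood size; needs
#'   `nrow(features) >= 3 * perplexity`.
#' @param n_iter gradient-descent iterations.
#' @param labels optional per-row annotation copied to the output.
#' @return data frame with columns `x`, `y` (and `label` if given).
#' @export
tsne_embed <- function(features, seed = 1, perplexity = 30, n_iter = 500,
                       labels = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3 * perplexity) {
    stop("t-SNE needs at least 3 * perplexity = ", 3 * perplexity,
         " samples; got ", n)
  }
  P <- tsne_affinities(features, perplexity)
  withr::with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exaggeration <- 4
    lr <- 100
    for (iter in seq_len(n_iter)) {
      Pe <- if (iter <= 100) P * exaggeration else P
      D2y <- as.matrix(stats::dist(Y))^2
      num <- 1 / (1 + D2y)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      momentum <- if (iter < 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - lr * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y), "-")
    }
    out <- data.frame(x = Y[, 1], y = Y[, 2])
    if (!is.null(labels)) out$label <- labels
    out
  })
}
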