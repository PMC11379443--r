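# Minimal neural-network engine backing the autoencoder and MLP heads.
#
# A network is a plain list of layer lists; each layer carries its type, fixed
# hyperparameters, trainable `params`, and (for batch-norm) running `buffers`.
# Convolutional activations are 4-d arrays (H, W, C, N); dense activations are
# matrices (N x D). All randomness (init, dropout, batching) goes through R's
# RNG so seeded runs are bit-reproducible on one machine.

nn_rnorm <- function(n, sd) array(stats::rnorm(n, sd = sd), dim = n)

#' @noRd
nn_conv <- function(in_ch, out_ch, kernel, stride, pad) {
  sd <- sqrt(2 / (kernel * kernel * in_ch))
  list(type = "conv", kernel = kernel, stride = stride, pad = pad,
       in_ch = in_ch, out_ch = out_ch,
       params = list(
         w = array(stats::rnorm(kernel * kernel * in_ch * out_ch, sd = sd),
                   dim = c(kernel, kernel, in_ch, out_ch)),
         b = numeric(out_ch)))
}

#' @noRd
nn_tconv <- function(in_ch, out_ch, kernel, stride, pad) {
  sd <- sqrt(2 / (kernel * kernel * in_ch))
  list(type = "tconv", kernel = kernel, stride = stride, pad = pad,
       in_ch = in_ch, out_ch = out_ch,
       params = list(
         w = array(stats::rnorm(kernel * kernel * out_ch * in_ch, sd = sd),
                   dim = c(kernel, kernel, out_ch, in_ch)),
         b = numeric(out_ch)))
}

#' @noRd
nn_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", ch = ch, eps = eps, momentum = momentum,
       params = list(gamma = rep(1, ch), beta = rep(0, ch)),
       buffers = list(run_mean = rep(0, ch), run_var = rep(1, ch)))
}

#' @noRd
nn_relu <- function() list(type = "relu", params = list())

#' @noRd
nn_sigmoid <- function() list(type = "sigmoid", params = list())

#' @noRd
nn_dropout <- function(p) {
  stopifnot(p >= 0, p < 1)
  list(type = "dropout", p = p, params = list())
}

#' @noRd
nn_linear <- function(in_dim, out_dim) {
  sd <- sqrt(2 / in_dim)
  list(type = "linear", in_dim = in_dim, out_dim = out_dim,
       params = list(w = matrix(stats::rnorm(in_dim * out_dim, sd = sd),
                                in_dim, out_dim),
                     b = numeric(out_dim)))
}

# A 4-d (H, W, C, N) activation is viewed as an (H*W) x (C*N) matrix (a free
# reshape in column-major order; channel index fastest across columns), so
# per-channel statistics come from column statistics without any aperm copy.
bn_col_stats <- function(colstat, C, N) rowMeans(matrix(colstat, C, N))

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      y <- cpp_conv2d_fwd(x, layer$params$w, layer$params$b,
                          layer$stride, layer$pad)
      list(y = y, cache = list(x = x))
    },
    tconv = {
      y <- cpp_tconv2d_fwd(x, layer$params$w, layer$params$b,
                           layer$stride, layer$pad)
      list(y = y, cache = list(x = x))
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask))
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = list(y = y))
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
        y <- x * mask
        list(y = y, cache = list(mask = mask))
      } else {
        list(y = x, cache = list(mask = NULL))
      }
    },
    linear = {
      y <- x %*% layer$params$w
      y <- sweep(y, 2, layer$params$b, "+")
      list(y = y, cache = list(x = x))
    },
    bn = {
      d <- dim(x)
      if (length(d) == 4) {
        C <- d[3]; N <- d[4]
        dim(x) <- c(d[1] * d[2], C * N)
      } else {
        # dense activations (N x C): one value per channel per sample
        C <- d[2]; N <- d[1]
        x <- t(x)
        dim(x) <- c(1, C * N)
      }
      m <- nrow(x) * N
      if (training) {
        mu <- bn_col_stats(colMeans(x), C, N)
        v <- bn_col_stats(colMeans(x^2), C, N) - mu^2
      } else {
        mu <- layer$buffers$run_mean
        v <- layer$buffers$run_var
      }
      invstd <- 1 / sqrt(v + layer$eps)
      # fused per-channel affine: y = x * a + b (recycled without sweep's
      # aperm copy)
      a <- layer$params$gamma * invstd
      b <- layer$params$beta - a * mu
      y <- x * rep(rep(a, N), each = nrow(x)) +
        rep(rep(b, N), each = nrow(x))
      upd <- NULL
      if (training) {
        mom <- layer$momentum
        upd <- list(run_mean = (1 - mom) * layer$buffers$run_mean + mom * mu,
                    run_var = (1 - mom) * layer$buffers$run_var + mom * v)
      }
      cache <- list(xm = x, mu = mu, invstd = invstd, d = d, m = m,
                    C = C, N = N)
      if (length(d) == 4) dim(y) <- d else y <- t(array(y, c(C, N)))
      list(y = y, cache = cache, buffer_update = upd)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, gy, need_gx = TRUE) {
  switch(layer$type,
    conv = {
      r <- cpp_conv2d_bwd(cache$x, layer$params$w, gy, layer$stride,
                          layer$pad, need_gx)
      list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    tconv = {
      r <- cpp_tconv2d_bwd(cache$x, layer$params$w, gy, layer$stride, layer$pad)
      list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    relu = list(gx = gy * cache$mask, grads = list()),
    sigmoid = list(gx = gy * cache$y * (1 - cache$y), grads = list()),
    dropout = {
      gx <- if (is.null(cache$mask)) gy else gy * cache$mask
      list(gx = gx, grads = list())
    },
    linear = {
      list(gx = gy %*% t(layer$params$w),
           grads = list(w = crossprod(cache$x, gy), b = colSums(gy)))
    },
    bn = {
      d <- cache$d; C <- cache$C; N <- cache$N; m <- cache$m
      gm <- gy
      if (length(d) == 4) dim(gm) <- c(d[1] * d[2], C * N)
      else { gm <- t(gm); dim(gm) <- c(1, C * N) }
      chan_sum <- function(colsums) rowSums(matrix(colsums, C, N))
      hw <- nrow(gm)
      expand <- function(v) rep(rep(v, N), each = hw)
      xhat <- (cache$xm - expand(cache$mu)) * expand(cache$invstd)
      ggamma <- chan_sum(colSums(gm * xhat))
      gbeta <- chan_sum(colSums(gm))
      coef <- layer$params$gamma * cache$invstd / m
      gxm <- (m * gm - expand(gbeta) - xhat * expand(ggamma)) * expand(coef)
      gx <- gxm
      if (length(d) == 4) dim(gx) <- d else gx <- t(array(gx, c(C, N)))
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    stop("unknown layer type: ", layer$type)
  )
}

#' Run a network forward
#'
#' @param net list of layers.
#' @param x input activation (4-d array or matrix).
#' @param training logical; batch-norm uses batch statistics and dropout is
#'   active when `TRUE`.
#' @param keep_cache keep per-layer caches for a subsequent backward pass.
#' @return list with `out`, `caches`, and `net` (running buffers updated when
#'   training).
#' @noRd
net_forward <- function(net, x, training = FALSE, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net)) else NULL
  for (i in seq_along(net)) {
    r <- layer_forward(net[[i]], x, training)
    x <- r$y
    if (keep_cache) caches[[i]] <- r$cache
    if (!is.null(r$buffer_update)) net[[i]]$buffers <- r$buffer_update
  }
  list(out = x, caches = caches, net = net)
}

#' @noRd
net_backward <- function(net, caches, gout) {
  grads <- vector("list", length(net))
  g <- gout
  for (i in rev(seq_along(net))) {
    r <- layer_backward(net[[i]], caches[[i]], g, need_gx = i > 1)
    grads[[i]] <- r$grads
    g <- r$gx
  }
  list(grads = grads, gx = g)
}

#' @noRd
net_n_params <- function(net) {
  sum(vapply(net, function(l) sum(vapply(l$params, length, 0L)), 0))
}

# ---- Adam optimiser over the nested layer-param structure -------------------

#' @noRd
adam_init <- function(net, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state <- lapply(net, function(l) lapply(l$params, function(p) {
    list(m = array(0, dim = dim(p) %||% length(p)),
         v = array(0, dim = dim(p) %||% length(p)))
  }))
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One Adam update. The parameter and moment buffers are updated in place
#' (single C++ pass); the training loops own them exclusively - nets entering
#' training are deep-copied first and checkpoints are deep-copied out (see
#' [net_copy_params()]).
#' @noRd
adam_step <- function(net, grads, opt) {
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(net)) {
    for (nm in names(net[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- opt$state[[i]][[nm]]
      cpp_adam_update(net[[i]]$params[[nm]], st$m, st$v, g, opt$lr,
                      opt$beta1, opt$beta2, bc1, bc2, opt$eps)
    }
  }
  list(net = net, opt = opt)
}

# deep copy of the trainable parameters (breaks aliasing with the in-place
# optimiser buffers)
net_copy_params <- function(net) {
  lapply(net, function(l) {
    l$params <- lapply(l$params, function(p) p + 0)
    l
  })
}
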