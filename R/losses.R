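# Reconstruction losses for autoencoder training.
#
# SSIM follows the standard luminance/contrast/structure form
#   SSIM(x, y) = (2 mu_x mu_y + c1)(2 s_xy + c2) /
#                ((mu_x^2 + mu_y^2 + c1)(s_x^2 + s_y^2 + c2))
# evaluated either over local uniform windows (default, side `window`) and
# averaged across positions/channels/samples, or globally per channel
# (`window = 0`). Moments are population (divide-by-m) moments. The analytic
# gradient with respect to the reconstruction backs the training loop and is
# validated against finite differences in the tests.

#' SSIM parameters
#'
#' @param window side length in pixels of the local uniform window; `0`
#'   computes one global statistic per channel.
#' @param dynamic_range value range `L` of the inputs (1 for min-max-normalized
#'   maps).
#' @param c1,c2 stabilizing constants; default `(0.01 L)^2` and `(0.03 L)^2`.
#' @return list of class `ssim_params`.
#' @export
ssim_params <- function(window = 11, dynamic_range = 1,
                        c1 = (0.01 * dynamic_range)^2,
                        c2 = (0.03 * dynamic_range)^2) {
  stopifnot(c1 > 0, c2 > 0, window >= 0)
  structure(list(window = as.integer(window), dynamic_range = dynamic_range,
                 c1 = c1, c2 = c2), class = "ssim_params")
}

as_act4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (length(d) < 4) {
    dim(x) <- c(d, rep(1, 4 - length(d)))
  }
  x
}

ssim_stats <- function(x, y, params) {
  win <- params$window
  if (win == 0) {
    d <- dim(x)
    slab <- function(z) {
      dim(z) <- c(d[1] * d[2], d[3] * d[4])
      z
    }
    xs <- slab(x); ys <- slab(y)
    mu_x <- colMeans(xs); mu_y <- colMeans(ys)
    list(mu_x = mu_x, mu_y = mu_y,
         xx = colMeans(xs^2), yy = colMeans(ys^2), xy = colMeans(xs * ys),
         global = TRUE)
  } else {
    list(mu_x = cpp_box_mean(x, win), mu_y = cpp_box_mean(y, win),
         xx = cpp_box_mean(x * x, win), yy = cpp_box_mean(y * y, win),
         xy = cpp_box_mean(x * y, win), global = FALSE)
  }
}

ssim_map <- function(st, params) {
  c1 <- params$c1; c2 <- params$c2
  sxy <- st$xy - st$mu_x * st$mu_y
  sxx <- st$xx - st$mu_x^2
  syy <- st$yy - st$mu_y^2
  a1 <- 2 * st$mu_x * st$mu_y + c1
  a2 <- 2 * sxy + c2
  b1 <- st$mu_x^2 + st$mu_y^2 + c1
  b2 <- sxx + syy + c2
  list(s = (a1 * a2) / (b1 * b2), a1 = a1, a2 = a2, b1 = b1, b2 = b2)
}

#' Structural similarity index (SSIM)
#'
#' @param x,y arrays of identical shape (2-d image, 3-d multi-channel image, or
#'   4-d batch); expected on the declared dynamic range.
#' @param params an [ssim_params()] object.
#' @return mean SSIM, a scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, params = ssim_params()) {
  stopifnot(identical(dim(x) %||% length(x), dim(y) %||% length(y)))
  x <- as_act4(x); y <- as_act4(y)
  mean(ssim_map(ssim_stats(x, y, params), params)$s)
}

#' SSIM reconstruction loss, `1 - SSIM`
#'
#' @inheritParams ssim
#' @return scalar loss in `[0, 2]`.
#' @export
ssim_loss <- function(x, y, params = ssim_params()) 1 - ssim(x, y, params)

# loss and gradient with respect to y (the reconstruction); x is the target
ssim_loss_grad <- function(x, y, params = ssim_params()) {
  d <- dim(y)
  x <- as_act4(x); y <- as_act4(y)
  st <- ssim_stats(x, y, params)
  sm <- ssim_map(st, params)
  npos <- length(sm$s)
  # dS/d(mu_y), dS/dB(y^2), dS/dB(xy) at each window position
  g_mu <- 2 * st$mu_x * (sm$a2 - sm$a1) / (sm$b1 * sm$b2) -
    2 * st$mu_y * sm$s * (1 / sm$b1 - 1 / sm$b2)
  g_yy <- -sm$s / sm$b2
  g_xy <- 2 * sm$a1 / (sm$b1 * sm$b2)
  scale <- -1 / npos
  if (st$global) {
    dd <- dim(y)
    m <- dd[1] * dd[2]
    expand <- function(g) {
      out <- matrix(rep(g / m, each = m), m, length(g))
      dim(out) <- dd
      out
    }
    gy <- scale * (expand(g_mu) + expand(g_yy) * 2 * y + expand(g_xy) * x)
  } else {
    win <- params$window
    H <- dim(y)[1]; W <- dim(y)[2]
    adj <- function(g) cpp_box_adjoint(g, win, H, W)
    gy <- scale * (adj(g_mu) + adj(g_yy) * 2 * y + adj(g_xy) * x)
  }
  dim(gy) <- d %||% length(gy)
  list(loss = 1 - mean(sm$s), grad = gy)
}

#' Mean squared error loss
#'
#' @param x,y arrays of identical shape.
#' @return mean of squared elementwise differences.
#' @export
mse_loss <- function(x, y) {
  stopifnot(identical(dim(x) %||% length(x), dim(y) %||% length(y)))
  mean((x - y)^2)
}

mse_loss_grad <- function(x, y) {
  list(loss = mean((x - y)^2), grad = 2 * (y - x) / length(y))
}

# binary cross-entropy on probabilities, with clamping for stability
bce_loss_grad <- function(p, y, eps = 1e-7) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  grad <- (pc - y) / (pc * (1 - pc)) / length(p)
  dim(grad) <- dim(p)
  list(loss = loss, grad = grad)
}

# binary cross-entropy on logits (numerically stable; gradient is bounded)
bce_logits_loss_grad <- function(z, y) {
  p <- 1 / (1 + exp(-z))
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  grad <- (p - y) / length(z)
  dim(grad) <- dim(z)
  list(loss = loss, grad = grad)
}
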