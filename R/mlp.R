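# Fully connected heads on the flattened latent features: a binary
# optimal/non-optimal classifier (sigmoid output, binary cross-entropy) and
# one single-output regressor per stimulation parameter (raw output, MSE on
# z-scored targets).

#' MLP head configuration
#'
#' The default taper is the 8-hidden-layer stack for the full-size latent:
#' 2304 -> 1024 -> 512 -> 256 -> 128 -> 64 -> 32 -> 16 -> 1, ReLU after every
#' layer but the last, dropout 25%/15%/15%/15% after the first four blocks.
#' For other latent sizes [mlp_widths()] builds a power-of-two taper with the
#' same 16 -> 1 ending.
#'
#' @param layer_widths width sequence from input dimension down to 1; must
#'   end `..., 16, 1`.
#' @param dropout_rates dropout after the first `length(dropout_rates)`
#'   blocks.
#' @param head `"classifier"` (sigmoid output) or `"regressor"` (raw output).
#' @return object of class `mlp_config`.
#' @export
mlp_config <- function(layer_widths = c(2304, 1024, 512, 256, 128, 64, 32,
                                        16, 1),
                       dropout_rates = c(0.25, 0.15, 0.15, 0.15),
                       head = c("classifier", "regressor")) {
  head <- match.arg(head)
  n <- length(layer_widths)
  if (n < 3 || layer_widths[n] != 1 || layer_widths[n - 1] != 16) {
    stop("layer widths must end with a 16 -> 1 output mapping")
  }
  stopifnot(all(layer_widths >= 1), all(dropout_rates >= 0),
            all(dropout_rates < 1))
  structure(list(layer_widths = layer_widths,
                 dropout_rates = dropout_rates, head = head),
            class = "mlp_config")
}

#' Width taper for an arbitrary latent size
#'
#' Halving powers of two from below the input width down to 16, then the
#' final 1-unit output.
#'
#' @param input_dim flattened latent length.
#' @export
mlp_widths <- function(input_dim) {
  top <- 2^floor(log2(max(input_dim - 1, 32)))
  c(input_dim, 2^seq(log2(top), 4), 1)
}

#' Build an MLP head
#'
#' @param config an [mlp_config()].
#' @param seed RNG seed for weight initialisation.
#' @return object of class `mlp_head`.
#' @export
build_head <- function(config, seed = 1) {
  stopifnot(inherits(config, "mlp_config"))
  w <- config$layer_widths
  net <- withr::with_seed(seed, {
    layers <- list()
    for (i in seq_len(length(w) - 1)) {
      layers <- c(layers, list(nn_linear(w[i], w[i + 1])))
      last <- i == length(w) - 1
      if (!last) layers <- c(layers, list(nn_relu()))
      if (i <= length(config$dropout_rates) && !last) {
        layers <- c(layers, list(nn_dropout(config$dropout_rates[i])))
      }
    }
    if (config$head == "classifier") layers <- c(layers, list(nn_sigmoid()))
    layers
  })
  structure(list(config = config, net = net,
                 normalization = list(mean = 0, sd = 1),
                 trained = FALSE, trace = numeric(0), best_epoch = NA),
            class = "mlp_head")
}

head_forward <- function(head, X, training = FALSE, keep_cache = FALSE) {
  stopifnot(is.matrix(X))
  if (ncol(X) != head$config$layer_widths[1]) {
    stop("input has ", ncol(X), " features; head expects ",
         head$config$layer_widths[1])
  }
  net_forward(head$net, X, training = training, keep_cache = keep_cache)
}

#' Classify latent features as optimal / non-optimal
#'
#' @param head a trained classifier `mlp_head`.
#' @param latent matrix of flattened latent features (rows = maps).
#' @param threshold decision threshold; a probability `>= threshold` is
#'   labelled optimal (ties go to optimal).
#' @return data frame with `probability` and logical `optimal`.
#' @export
classify_settings <- function(head, latent, threshold = 0.5) {
  stopifnot(head$config$head == "classifier")
  p <- as.numeric(head_forward(head, latent)$out)
  data.frame(probability = p, optimal = p >= threshold)
}

#' Predict a stimulation parameter from latent features
#'
#' Returns the denormalized prediction in physical units (V, Hz or mm,
#' according to the target the head was trained on).
#'
#' @param head a trained regressor `mlp_head`.
#' @param latent matrix of flattened latent features.
#' @return numeric vector of predictions.
#' @export
predict_parameter <- function(head, latent) {
  stopifnot(head$config$head == "regressor")
  raw <- as.numeric(head_forward(head, latent)$out)
  raw * head$normalization$sd + head$normalization$mean
}

#' Train an MLP head with per-epoch validation checkpointing
#'
#' Classifiers minimise binary cross-entropy and checkpoint the epoch of
#' highest validation accuracy; regressors are fitted on z-scored targets
#' with MSE and checkpoint the lowest validation MSE. Ties resolve to the
#' earliest epoch. Regression targets are normalized with the training-set
#' mean/sd (stored on the head for denormalization).
#'
#' @param head an `mlp_head` from [build_head()].
#' @param X training feature matrix; `y` its targets (0/1 for classifiers,
#'   physical units for regressors).
#' @param X_val,y_val validation set used for checkpoint selection (defaults
#'   to the training set).
#' @param epochs,learning_rate,batch_size optimisation settings.
#' @param seed RNG seed (shuffling and dropout).
#' @return the trained head, carrying the best-epoch weights, `trace` of the
#'   per-epoch validation score, and `best_epoch`.
#' @export
train_head <- function(head, X, y, X_val = X, y_val = y, epochs = 100,
                       learning_rate = 1e-3, batch_size = 8, seed = 1) {
  stopifnot(nrow(X) == length(y), nrow(X_val) == length(y_val), epochs >= 1)
  classifier <- head$config$head == "classifier"
  if (classifier) {
    y_fit <- y
    y_val_fit <- y_val
  } else {
    mu <- mean(y)
    sdv <- stats::sd(y)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    head$normalization <- list(mean = mu, sd = sdv)
    y_fit <- (y - mu) / sdv
    y_val_fit <- (y_val - mu) / sdv
  }
  # classifiers are optimised on the pre-sigmoid logits (the numerically
  # stable form of binary cross-entropy); the sigmoid stays in the stored
  # head for inference
  net <- net_copy_params(if (classifier) head$net[-length(head$net)]
                         else head$net)
  opt <- adam_init(net, lr = learning_rate)
  trace <- numeric(epochs)
  best <- NULL
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(X))
      for (start in seq(1, nrow(X), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, nrow(X))]
        xb <- X[idx, , drop = FALSE]
        yb <- y_fit[idx]
        fw <- net_forward(net, xb, training = TRUE, keep_cache = TRUE)
        net <- fw$net
        lg <- if (classifier) bce_logits_loss_grad(fw$out, yb)
              else mse_loss_grad(matrix(yb), fw$out)
        if (!is.finite(lg$loss)) stop("non-finite loss at epoch ", ep)
        bw <- net_backward(net, fw$caches, lg$grad)
        upd <- adam_step(net, bw$grads, opt)
        net <- upd$net
        opt <- upd$opt
      }
      pv <- net_forward(net, X_val, training = FALSE)$out
      trace[ep] <- if (classifier) mean((pv >= 0) == (y_val_fit >= 0.5))
                   else mean((pv - y_val_fit)^2)
      improved <- is.null(best) ||
        (if (classifier) trace[ep] > best$score else trace[ep] < best$score)
      if (improved) {
        best <- list(score = trace[ep], net = net_copy_params(net),
                     epoch = ep)
      }
    }
  })
  best_ep <- select_best_checkpoint(trace, if (classifier) "max" else "min")
  stopifnot(best_ep == best$epoch)  # earliest-tie bookkeeping agrees
  head$net <- if (classifier) c(best$net, list(nn_sigmoid())) else best$net
  head$trace <- trace
  head$best_epoch <- best_ep
  head$trained <- TRUE
  head
}

#' Select the checkpoint epoch from a validation trace
#'
#' Argmax for accuracy-like scores, argmin for error-like scores; ties
#' resolve to the earliest epoch.
#'
#' @param validation_trace numeric per-epoch validation scores.
#' @param criterion `"max"` or `"min"`.
#' @return epoch index.
#' @export
select_best_checkpoint <- function(validation_trace, criterion = c("max",
                                                                   "min")) {
  criterion <- match.arg(criterion)
  stopifnot(length(validation_trace) >= 1)
  if (criterion == "max") which.max(validation_trace)
  else which.min(validation_trace)
}
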