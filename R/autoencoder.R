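# Convolutional autoencoder feature extractor.
#
# The 91 axial slices of a preprocessed response map enter as the input
# channels of a 2-d convolutional stack: a first stride-1 block compresses
# the slices to a single channel, five stride-2 blocks (kernel 4, padding 1)
# halve the spatial side while widening to 256 channels, giving a 256 x 3 x 3
# latent code for 96 x 96 slices. The decoder mirrors this with five
# transposed-convolution blocks ending in 91 output channels. Every block is
# convolution -> ReLU -> batch-norm. Training minimises `1 - SSIM` between
# input and reconstruction with Adam.

#' Autoencoder configuration
#'
#' The default is the full-size architecture: encoder filters
#' 1, 16, 32, 64, 128, 256 (first block kernel 3 stride 1, the rest kernel 4
#' stride 2), decoder filters 128, 64, 32, 16, 91 (kernel 4 stride 2),
#' input 96 x 96 with 91 slice-channels, latent 256 x 3 x 3.
#'
#' @param input_shape `(H, W, slices)` of the preprocessed maps.
#' @param encoder_filters channel widths of the encoder blocks; the first
#'   entry is the stride-1 slice-compression block.
#' @param decoder_filters channel widths of the decoder blocks; the last
#'   entry must equal the slice count.
#' @param first_kernel,down_kernel,up_kernel kernel sizes (strides 1/2/2,
#'   padding 1 throughout - the only choice making the spatial ladder exact).
#' @param output_sigmoid clamp the reconstruction with a sigmoid (off by
#'   default; outputs are compared to `[0, 1]` targets directly).
#' @return object of class `ae_config`.
#' @export
ae_config <- function(input_shape = c(96, 96, 91),
                      encoder_filters = c(1, 16, 32, 64, 128, 256),
                      decoder_filters = c(128, 64, 32, 16, 91),
                      first_kernel = 3, down_kernel = 4, up_kernel = 4,
                      output_sigmoid = FALSE) {
  stopifnot(length(input_shape) == 3, input_shape[1] == input_shape[2],
            length(encoder_filters) >= 3,
            length(decoder_filters) == length(encoder_filters) - 1)
  n_down <- length(encoder_filters) - 1
  side <- input_shape[1]
  if (side %% 2^n_down != 0) {
    stop("spatial side ", side, " is not divisible by 2^", n_down)
  }
  latent_side <- side / 2^n_down
  if (latent_side < 3) {
    stop("latent side would be ", latent_side, " (< 3); too many ",
         "downsampling stages for side ", side)
  }
  if (decoder_filters[length(decoder_filters)] != input_shape[3]) {
    stop("last decoder filter count (",
         decoder_filters[length(decoder_filters)],
         ") must equal the slice count (", input_shape[3], ")")
  }
  structure(list(input_shape = input_shape,
                 encoder_filters = encoder_filters,
                 decoder_filters = decoder_filters,
                 first_kernel = first_kernel, down_kernel = down_kernel,
                 up_kernel = up_kernel, output_sigmoid = output_sigmoid,
                 latent_shape = c(latent_side, latent_side,
                                  encoder_filters[length(encoder_filters)])),
            class = "ae_config")
}

#' Desk-scale autoencoder configuration
#'
#' A reduced preset for CPU-scale runs: 48 x 48 slices and one fewer
#' downsampling stage (48 -> 24 -> 12 -> 6 -> 3), with the interior filter
#' widths trimmed but the full 256-channel bottleneck kept, so the latent is
#' 256 x 3 x 3 (flattened length 2304) exactly as in the full-size
#' configuration. The full-size [ae_config()] stays the default for
#' production runs.
#'
#' @inheritParams ae_config
#' @export
ae_config_desk <- function(input_shape = c(48, 48, 91),
                           output_sigmoid = FALSE) {
  ae_config(input_shape = input_shape,
            encoder_filters = c(1, 16, 32, 64, 256),
            decoder_filters = c(64, 32, 16, input_shape[3]),
            output_sigmoid = output_sigmoid)
}

ae_build_net <- function(config) {
  slices <- config$input_shape[3]
  first <- nn_conv(slices, config$encoder_filters[1], config$first_kernel,
                   stride = 1, pad = (config$first_kernel - 1) / 2)
  # the network input is min-max normalized to [0, 1] (mean ~ 0.5), not
  # centred; cancel the first convolution's mean-input response and leave a
  # small positive margin so its ReLU starts alive regardless of the weight
  # draw (critical for the single-filter first block, which cannot recover
  # once dead)
  first$params$b <- 0.1 - 0.5 * apply(first$params$w, 4, sum)
  enc <- list(first, nn_relu(), nn_bn(config$encoder_filters[1]))
  for (i in seq_len(length(config$encoder_filters) - 1)) {
    enc <- c(enc, list(
      nn_conv(config$encoder_filters[i], config$encoder_filters[i + 1],
              config$down_kernel, stride = 2, pad = 1),
      nn_relu(), nn_bn(config$encoder_filters[i + 1])))
  }
  dec <- list()
  in_ch <- config$encoder_filters[length(config$encoder_filters)]
  nf <- length(config$decoder_filters)
  for (i in seq_len(nf)) {
    f <- config$decoder_filters[i]
    dec <- c(dec, list(nn_tconv(in_ch, f, config$up_kernel, stride = 2,
                                pad = 1)))
    # the output block is the bare transposed convolution: its values are
    # compared to the [0, 1] targets directly (no activation clamp); its
    # bias starts at the target midpoint so training begins
    # luminance-matched and the gradient signal points at map structure
    if (i < nf) {
      dec <- c(dec, list(nn_relu(), nn_bn(f)))
    } else {
      dec[[length(dec)]]$params$b[] <- 0.5
      dec[[length(dec)]]$params$w <- dec[[length(dec)]]$params$w * 0.1
    }
    in_ch <- f
  }
  if (config$output_sigmoid) dec <- c(dec, list(nn_sigmoid()))
  list(encoder = enc, decoder = dec)
}

#' Initialise an (untrained) autoencoder
#'
#' @param config an [ae_config()].
#' @param seed RNG seed for the weight initialisation.
#' @return object of class `dbs_ae`.
#' @export
ae_init <- function(config = ae_config(), seed = 1) {
  nets <- withr::with_seed(seed, ae_build_net(config))
  structure(list(config = config, encoder = nets$encoder,
                 decoder = nets$decoder, loss_trace = numeric(0),
                 trained = FALSE),
            class = "dbs_ae")
}

#' @export
print.dbs_ae <- function(x, ...) {
  cat("Convolutional autoencoder: input ",
      paste(x$config$input_shape, collapse = "x"), " (slices as channels), ",
      "latent ", paste(rev(x$config$latent_shape), collapse = "x"),
      ", ", ae_n_params(x), " parameters, ",
      if (x$trained) paste0("trained (", length(x$loss_trace), " epochs)")
      else "untrained", "\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters of an autoencoder
#' @param ae a `dbs_ae`.
#' @export
ae_n_params <- function(ae) {
  net_n_params(ae$encoder) + net_n_params(ae$decoder)
}

as_batch <- function(volumes, input_shape) {
  d <- dim(volumes)
  if (length(d) == 3) dim(volumes) <- c(d, 1)
  d <- dim(volumes)
  if (!all(d[1:3] == input_shape)) {
    stop("volumes are ", paste(d[1:3], collapse = "x"),
         "; the autoencoder expects ", paste(input_shape, collapse = "x"))
  }
  volumes
}

#' Encode volumes to latent features
#'
#' Runs the (frozen) encoder in inference mode - batch-norm uses running
#' statistics, so encoding is a pure function of the input.
#'
#' @param ae a `dbs_ae`.
#' @param volumes 3-d volume or 4-d batch, shape `config$input_shape`
#'   (x slices last).
#' @return matrix `n x prod(latent_shape)` of flattened latent codes, with
#'   the latent array shape in `attr(, "latent_shape")`.
#' @export
ae_encode <- function(ae, volumes) {
  x <- as_batch(volumes, ae$config$input_shape)
  z <- net_forward(ae$encoder, x, training = FALSE)$out
  d <- dim(z)
  out <- t(matrix(z, prod(d[1:3]), d[4]))
  attr(out, "latent_shape") <- d[1:3]
  out
}

#' Decode latent features to volumes
#'
#' @param ae a `dbs_ae`.
#' @param latent matrix of flattened codes (as from [ae_encode()]) or a
#'   latent array.
#' @return 4-d array of reconstructions `(H, W, slices, n)`.
#' @export
ae_decode <- function(ae, latent) {
  ls <- ae$config$latent_shape
  if (is.matrix(latent)) {
    if (ncol(latent) != prod(ls)) {
      stop("latent length ", ncol(latent), "; expected ", prod(ls))
    }
    latent <- array(t(latent), dim = c(ls, nrow(latent)))
  }
  d <- dim(latent)
  if (length(d) == 3) dim(latent) <- c(d, 1)
  if (!all(dim(latent)[1:3] == ls)) {
    stop("latent shape ", paste(dim(latent)[1:3], collapse = "x"),
         "; expected ", paste(ls, collapse = "x"))
  }
  net_forward(ae$decoder, latent, training = FALSE)$out
}

#' Train the autoencoder
#'
#' Minimises the reconstruction loss (default `1 - SSIM`) over all volumes
#' with Adam; one shuffled pass over the data per epoch. The mean epoch loss
#' is recorded in `loss_trace`. Seeded runs are bit-reproducible on one
#' machine.
#'
#' @param ae a `dbs_ae` (freshly initialised or to be trained further).
#' @param volumes 4-d array `(H, W, slices, n)` of preprocessed maps.
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param loss `"ssim"` or `"mse"`.
#' @param ssim_window window for the SSIM loss (see [ssim_params()]).
#' @param seed RNG seed (shuffling, dropout - none here - and any noise).
#' @param verbose print the per-epoch loss.
#' @return the trained `dbs_ae` with `loss_trace` filled.
#' @export
train_autoencoder <- function(ae, volumes, epochs = 250,
                              learning_rate = 1e-4, batch_size = 8,
                              loss = c("ssim", "mse"), ssim_window = 11,
                              seed = 1, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1)
  x_all <- as_batch(volumes, ae$config$input_shape)
  n <- dim(x_all)[4]
  stopifnot(n >= 1)
  sp <- ssim_params(window = ssim_window)
  loss_fn <- if (loss == "ssim") function(x, y) ssim_loss_grad(x, y, sp)
             else mse_loss_grad

  net <- net_copy_params(c(ae$encoder, ae$decoder))
  n_enc <- length(ae$encoder)
  opt <- adam_init(net, lr = learning_rate)
  trace <- numeric(epochs)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- x_all[, , , idx, drop = FALSE]
        fw <- net_forward(net, xb, training = TRUE, keep_cache = TRUE)
        net <- fw$net
        lg <- loss_fn(xb, fw$out)
        if (!is.finite(lg$loss)) {
          stop("non-finite training loss at epoch ", ep,
               " (batch starting at ", start, ")")
        }
        bw <- net_backward(net, fw$caches, lg$grad)
        upd <- adam_step(net, bw$grads, opt)
        net <- upd$net
        opt <- upd$opt
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      trace[ep] <- ep_loss / n
      if (verbose) {
        message(sprintf("epoch %3d/%d  %s loss %.5f", ep, epochs, loss,
                        trace[ep]))
      }
    }
  })
  ae$encoder <- net[seq_len(n_enc)]
  ae$decoder <- net[(n_enc + 1):length(net)]
  ae$loss_trace <- c(ae$loss_trace, trace)
  ae$trained <- TRUE
  ae_recalibrate_bn(ae, x_all)
}

# Replace the batch-norm running statistics with full-dataset statistics
# (one forward pass with momentum 1). ReLU-sparse channels make the
# momentum-averaged minibatch statistics a poor inference-time estimate on
# small datasets; recalibrating keeps inference-mode encoding a well-scaled
# pure function of the input.
ae_recalibrate_bn <- function(ae, volumes) {
  set_mom <- function(net, m) {
    lapply(net, function(l) {
      if (l$type == "bn") l$momentum <- m
      l
    })
  }
  n_enc <- length(ae$encoder)
  net <- set_mom(c(ae$encoder, ae$decoder), 1)
  net <- net_forward(net, volumes, training = TRUE)$net
  net <- set_mom(net, 0.1)
  ae$encoder <- net[seq_len(n_enc)]
  ae$decoder <- net[(n_enc + 1):length(net)]
  ae
}

# stable hash of the autoencoder weights (frozen-weights contract checks)
ae_weight_checksum <- function(ae) {
  vals <- unlist(lapply(c(ae$encoder, ae$decoder), function(l) {
    lapply(l$params, as.numeric)
  }), use.names = FALSE)
  sum(vals * seq_along(vals) %% 97)
}
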