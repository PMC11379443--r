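# Autoencoder: shape ladder, config validation, round trips, training
# descent, determinism and the frozen-weights contract.

test_that("the full-size architecture maps 96x96x91 to a 256x3x3 latent and back", {
  cfg <- ae_config()
  expect_equal(cfg$latent_shape, c(3, 3, 256))
  expect_equal(cfg$encoder_filters, c(1, 16, 32, 64, 128, 256))
  expect_equal(cfg$decoder_filters, c(128, 64, 32, 16, 91))
})

test_that("the spatial ladder halves exactly at every downsampling stage", {
  ae <- ae_init(ae_config(input_shape = c(32, 32, 5),
                          encoder_filters = c(1, 8, 16, 32),
                          decoder_filters = c(16, 8, 5)), seed = 1)
  x <- array(runif(32 * 32 * 5), c(32, 32, 5, 1))
  sides <- integer(0)
  act <- x
  for (l in ae$encoder) {
    act <- dbsfmri:::layer_forward(l, act, FALSE)$y
    if (l$type == "conv") sides <- c(sides, dim(act)[1])
  }
  expect_equal(sides, c(32, 16, 8, 4))
})

test_that("a custom uncapped desk-scale config reaches a 256x3x3 latent from 48x48", {
  # shape arithmetic: 48 -> 24 -> 12 -> 6 -> 3 over four stride-2 stages
  cfg <- ae_config(input_shape = c(48, 48, 91),
                   encoder_filters = c(1, 16, 32, 64, 256),
                   decoder_filters = c(64, 32, 16, 91))
  expect_equal(cfg$latent_shape, c(3, 3, 256))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(ae_config(input_shape = c(48, 48, 91)), "divisible")
  expect_error(ae_config(input_shape = c(96, 96, 91),
                         encoder_filters = c(1, 8, 16, 32, 64, 128, 256),
                         decoder_filters = c(128, 64, 32, 16, 8, 91)),
               "latent side|divisible")
  expect_error(ae_config(input_shape = c(96, 96, 91),
                         decoder_filters = c(128, 64, 32, 16, 90)),
               "slice count")
})

test_that("encode / decode round-trip shapes and reject mismatched input", {
  fx <- tiny_ae_fixture(n = 4)
  ae <- ae_init(fx$config, seed = 2)
  z <- ae_encode(ae, fx$volumes)
  expect_equal(dim(z), c(4, prod(fx$config$latent_shape)))
  expect_true(all(is.finite(z)))
  xr <- ae_decode(ae, z)
  expect_equal(dim(xr), c(16, 16, 5, 4))
  expect_error(ae_encode(ae, array(0, c(8, 8, 5, 1))), "expects")
  expect_error(ae_decode(ae, matrix(0, 1, 7)), "expected")
  # all-zero input still yields a finite latent
  expect_true(all(is.finite(ae_encode(ae, array(0, c(16, 16, 5, 1))))))
})

test_that("parameter count is a pure function of the configuration", {
  fx <- tiny_ae_fixture()
  n1 <- ae_n_params(ae_init(fx$config, seed = 1))
  n2 <- ae_n_params(ae_init(fx$config, seed = 99))
  expect_equal(n1, n2)
})

test_that("training reduces the reconstruction loss and is seed-reproducible", {
  fx <- tiny_ae_fixture(n = 10)
  ae <- ae_init(fx$config, seed = 3)
  tr1 <- train_autoencoder(ae, fx$volumes, epochs = 12,
                           learning_rate = 1e-3, seed = 4)
  expect_length(tr1$loss_trace, 12)
  expect_lt(tail(tr1$loss_trace, 1), tr1$loss_trace[1])
  tr2 <- train_autoencoder(ae, fx$volumes, epochs = 12,
                           learning_rate = 1e-3, seed = 4)
  expect_identical(tr1$loss_trace, tr2$loss_trace)
  # epochs = 1 gives a length-1 trace
  expect_length(train_autoencoder(ae, fx$volumes, epochs = 1,
                                  seed = 5)$loss_trace, 1)
})

test_that("a trained encoder is a pure function (frozen-weights contract)", {
  fx <- tiny_ae_fixture(n = 8)
  ae <- train_autoencoder(ae_init(fx$config, seed = 5), fx$volumes,
                          epochs = 3, learning_rate = 1e-3, seed = 6)
  z1 <- ae_encode(ae, fx$volumes[, , , 1:2])
  z2 <- ae_encode(ae, fx$volumes[, , , 1:2])
  expect_identical(z1, z2)
  # encoding one map alone equals its row in the batch encoding
  z_solo <- ae_encode(ae, fx$volumes[, , , 1])
  expect_equal(as.numeric(z_solo), as.numeric(z1[1, ]), tolerance = 1e-12)
})
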