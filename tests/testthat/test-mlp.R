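# MLP heads: architecture validation, decision rule, determinism, sanity
# fits, and checkpoint selection.

test_that("the default head has eight weight layers ending 16 -> 1", {
  cfg <- mlp_config()
  expect_equal(cfg$layer_widths,
               c(2304, 1024, 512, 256, 128, 64, 32, 16, 1))
  clf <- build_head(cfg, seed = 1)
  linears <- Filter(function(l) l$type == "linear", clf$net)
  expect_length(linears, 8)
  last <- linears[[8]]
  expect_equal(dim(last$params$w), c(16, 1))
  expect_error(mlp_config(c(64, 32, 8, 1)), "16")
  expect_error(mlp_config(c(64, 32, 16, 2)), "16")
})

test_that("parameter count is deterministic given the configuration", {
  cfg <- mlp_config(c(50, 32, 16, 1))
  n <- function(seed) {
    dbsfmri:::net_n_params(build_head(cfg, seed = seed)$net)
  }
  expect_equal(n(1), n(2))
  expect_equal(n(1), 50 * 32 + 32 + 32 * 16 + 16 + 16 * 1 + 1)
})

test_that("classifier output is a probability and the >= 0.5 tie goes to optimal", {
  clf <- build_head(mlp_config(c(10, 32, 16, 1), head = "classifier"),
                    seed = 3)
  withr::with_seed(4, X <- matrix(rnorm(50), 5, 10))
  res <- classify_settings(clf, X)
  expect_true(all(res$probability > 0 & res$probability < 1))
  # forcing a probability of exactly 0.5 labels optimal under the ">=" rule
  fake <- clf
  for (i in seq_along(fake$net)) {
    if (fake$net[[i]]$type == "linear") {
      fake$net[[i]]$params$w[] <- 0
      fake$net[[i]]$params$b[] <- 0
    }
  }
  expect_true(all(classify_settings(fake, X)$probability == 0.5))
  expect_true(all(classify_settings(fake, X)$optimal))
  # inference is deterministic (dropout inactive)
  expect_identical(classify_settings(clf, X), classify_settings(clf, X))
})

test_that("training separates a linearly separable toy problem perfectly", {
  withr::with_seed(5, {
    X <- matrix(rnorm(400), 40, 10)
    y <- as.numeric(X[, 1] > 0)
    X[, 1] <- X[, 1] + 2 * sign(X[, 1])
  })
  clf <- build_head(mlp_config(c(10, 32, 16, 1), head = "classifier"),
                    seed = 6)
  clf <- train_head(clf, X, y, epochs = 60, seed = 7)
  expect_equal(mean(classify_settings(clf, X)$optimal == (y == 1)), 1)
})

test_that("a constant-target regressor predicts the constant", {
  withr::with_seed(8, X <- matrix(rnorm(300), 30, 10))
  y <- rep(3, 30)
  reg <- build_head(mlp_config(c(10, 32, 16, 1), head = "regressor"),
                    seed = 9)
  reg <- train_head(reg, X, y, epochs = 150, seed = 10)
  expect_lt(rmse(predict_parameter(reg, X), rep(3, 30)), 0.2)
  # normalization round trip
  v <- c(-2.5, 0, 7.1)
  expect_equal((v - reg$normalization$mean) / reg$normalization$sd *
                 reg$normalization$sd + reg$normalization$mean, v,
               tolerance = 1e-12)
})

test_that("a regressor recovers a noiseless linear mapping well", {
  withr::with_seed(11, {
    X <- matrix(rnorm(600), 60, 10)
    y <- 2 + 1.5 * X[, 1] - X[, 2]
  })
  reg <- build_head(mlp_config(c(10, 32, 16, 1), head = "regressor"),
                    seed = 12)
  reg <- train_head(reg, X, y, epochs = 150, seed = 13)
  err <- rmse(y, predict_parameter(reg, X))
  expect_lt(err, 0.05 * diff(range(y)))
})

test_that("best-checkpoint selection follows the declared tie and direction rules", {
  expect_equal(select_best_checkpoint(c(0.6, 0.9, 0.9, 0.7), "max"), 2)
  expect_equal(select_best_checkpoint(c(0.1, 0.2, 0.3), "max"), 3)
  expect_equal(select_best_checkpoint(c(0.5, 0.2, 0.3), "min"), 2)
  expect_equal(select_best_checkpoint(c(0.2, 0.2), "min"), 1)
})

test_that("the stored classifier corresponds to its recorded best epoch", {
  withr::with_seed(14, {
    X <- matrix(rnorm(200), 20, 10)
    y <- rbinom(20, 1, 0.5)
  })
  clf <- build_head(mlp_config(c(10, 32, 16, 1), head = "classifier"),
                    seed = 15)
  clf <- train_head(clf, X, y, epochs = 10, seed = 16)
  expect_equal(clf$best_epoch, which.max(clf$trace))
  # stored weights reproduce the recorded best validation accuracy
  acc <- mean(classify_settings(clf, X)$optimal == (y == 1))
  expect_equal(acc, clf$trace[clf$best_epoch])
})
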