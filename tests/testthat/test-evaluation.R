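# Evaluation metrics against brute-force oracles, curve properties, cosine
# similarity, and the t-SNE embedding.

test_that("confusion-matrix metrics match the arithmetic definitions", {
  # counts (TP, FP, FN, TN) = (3, 1, 1, 5)
  labels <- c(rep(1, 4), rep(0, 6))
  probs <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.1, 0.4)
  rep_ <- classification_metrics(labels, probs)
  expect_equal(c(rep_$tp, rep_$fp, rep_$fn, rep_$tn), c(3, 1, 1, 5))
  expect_equal(rep_$accuracy, 0.8)
  expect_equal(rep_$precision, 0.75)
  expect_equal(rep_$recall, 0.75)
  expect_equal(rep_$f1, 0.75)
})

test_that("perfect separation yields accuracy 1 and ROC AUC 1", {
  labels <- c(1, 1, 1, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  rep_ <- classification_metrics(labels, probs)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$roc_auc, 1)
  expect_equal(rep_$pr_auc, 1)
})

test_that("ROC/PR AUC agrees with pROC on random data and is 0.5 under the null", {
  skip_if_not_installed("pROC")
  withr::with_seed(30, {
    labels <- rbinom(300, 1, 0.4)
    probs <- runif(300)
  })
  rep_ <- classification_metrics(labels, probs)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                        direction = "<",
                                        levels = c(0, 1))))
  expect_equal(rep_$roc_auc, ref, tolerance = 1e-10)
  withr::with_seed(31, {
    labels <- rep(c(0, 1), 1000)
    probs <- runif(2000)
  })
  expect_equal(classification_metrics(labels, probs)$roc_auc, 0.5,
               tolerance = 0.05)
})

test_that("single-class input returns scalar metrics but refuses curves", {
  rep_ <- classification_metrics(c(1, 1, 1), c(0.9, 0.8, 0.4))
  expect_equal(rep_$recall, 2 / 3)
  expect_null(rep_$roc)
  expect_match(rep_$curves_skipped, "both classes")
})

test_that("rmse matches hand arithmetic and dominates the absolute mean error", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  withr::with_seed(32, {
    for (rep in 1:5) {
      a <- rnorm(30); b <- rnorm(30)
      expect_gte(rmse(a, b), abs(mean(a - b)) - 1e-12)
    }
  })
  expect_error(rmse(numeric(0), numeric(0)))
})

test_that("tolerance accuracy applies the relative-deviation rule", {
  expect_equal(tolerance_accuracy(c(1, 2, 3), c(1, 2, 3), 0.1), 1)
  # 2.25 vs 2.0 is 12.5% off: outside 10%, inside 15%
  expect_equal(tolerance_accuracy(2, 2.25, 0.10), 0)
  expect_equal(tolerance_accuracy(2, 2.25, 0.15), 1)
  # zero truths only accurate for exactly-zero predictions
  expect_equal(tolerance_accuracy(c(0, 0), c(0, 0.01), 0.15), 0.5)
  withr::with_seed(33, {
    for (rep in 1:5) {
      yt <- rnorm(40); yp <- yt + rnorm(40, sd = 0.2)
      for (tol in c(0.05, 0.1, 0.15)) {
        expect_equal(tolerance_accuracy(yt, yp, tol),
                     oracle_tolerance(yt, yp, tol))
      }
      # monotone non-decreasing in the tolerance
      expect_lte(tolerance_accuracy(yt, yp, 0.10),
                 tolerance_accuracy(yt, yp, 0.15))
    }
  })
})

test_that("cosine similarity index handles the canonical vector cases", {
  v <- matrix(c(1, 2, 3), 1)
  expect_equal(cosine_similarity_index(v, v), 1)
  expect_equal(cosine_similarity_index(v, -v), -1)
  expect_equal(cosine_similarity_index(matrix(c(1, 0), 1),
                                       matrix(c(0, 1), 1)), 0)
  expect_warning(res <- cosine_similarity_index(matrix(0, 1, 3), v),
                 "zero-norm")
  expect_true(is.na(res))
  # group-mean mode compares the two mean vectors
  A <- rbind(c(1, 0), c(0, 1))
  B <- rbind(c(1, 0), c(1, 0))
  expect_equal(cosine_similarity_index(A, B, "group-mean"),
               sum(c(0.5, 0.5) * c(1, 0)) / (sqrt(0.5) * 1))
})

test_that("t-SNE embeds points deterministically and separates planted clusters", {
  skip_if_not_installed("cluster")
  withr::with_seed(34, {
    X <- rbind(matrix(rnorm(30 * 10, mean = 0), 30, 10),
               matrix(rnorm(30 * 10, mean = 6), 30, 10))
  })
  lab <- rep(c(0, 1), each = 30)
  emb <- tsne_embed(X, seed = 35, perplexity = 10, n_iter = 300,
                    labels = lab)
  expect_equal(nrow(emb), 60)
  expect_identical(emb, tsne_embed(X, seed = 35, perplexity = 10,
                                   n_iter = 300, labels = lab))
  sil <- cluster::silhouette(lab + 1, dist(cbind(emb$x, emb$y)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(tsne_embed(X[1:10, ], perplexity = 10), "at least")
})

test_that("flip robustness on symmetric inputs gives CSI 1", {
  fx <- tiny_ae_fixture(n = 6)
  ae <- train_autoencoder(ae_init(fx$config, seed = 40), fx$volumes,
                          epochs = 2, learning_rate = 1e-3, seed = 41)
  # left-right symmetric volumes: flipped latents must equal nominal ones
  sym <- fx$volumes
  sym <- (sym + sym[rev(seq_len(dim(sym)[1])), , , , drop = FALSE]) / 2
  rep_ <- flip_robustness_report(ae, sym, labels = rep(c(0, 1), 3),
                                 n_shuffles = 20, seed = 42)
  expect_equal(rep_$groups$optimal$csi_paired, 1, tolerance = 1e-10)
  expect_equal(rep_$groups$non_optimal$csi_paired, 1, tolerance = 1e-10)
  expect_equal(rep_$latent_nominal, rep_$latent_flipped, tolerance = 1e-10)
})
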