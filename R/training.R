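# Two-stage training: the autoencoder is fitted unsupervised on all nominal
# maps (stage 1), then frozen; latent features are extracted once and the MLP
# classifier and five parameter regressors are trained per fold of a
# stratified k-fold split with per-epoch best-checkpoint selection (stage 2).

#' Training plan
#'
#' @param ae_epochs autoencoder epochs (stage 1).
#' @param mlp_epochs epochs per MLP head per fold (stage 2).
#' @param folds number of cross-validation folds.
#' @param ae_lr,mlp_lr Adam learning rates.
#' @param batch_size minibatch size for both stages.
#' @param ssim_window SSIM window for the reconstruction loss.
#' @param seed global seed; all stage seeds are derived from it and recorded.
#' @param group_by_patient keep all maps of a patient in one fold (off by
#'   default: the reference protocol stratifies over maps, which permits
#'   within-patient leakage - see the package vignette).
#' @return object of class `training_plan`.
#' @export
training_plan <- function(ae_epochs = 250, mlp_epochs = 100, folds = 5,
                          ae_lr = 1e-4, mlp_lr = 1e-3, batch_size = 8,
                          ssim_window = 11, seed = 1,
                          group_by_patient = FALSE, mlp_widths = NULL) {
  stopifnot(folds >= 2, ae_epochs >= 1, mlp_epochs >= 1)
  structure(as.list(environment()), class = "training_plan")
}

#' Desk-scale training plan
#'
#' Reduced settings for CPU-scale runs: 30 autoencoder epochs at learning
#' rate 1e-3, 40 head epochs, 5 folds, and MLP interior widths trimmed to a
#' 2304 -> 256 -> 128 -> 64 -> 32 -> 16 -> 1 taper (the full-size
#' architecture keeps the published 8-hidden-layer stack).
#' @inheritParams training_plan
#' @export
training_plan_desk <- function(seed = 1, group_by_patient = FALSE) {
  training_plan(ae_epochs = 30, mlp_epochs = 40, folds = 5, ae_lr = 1e-3,
                seed = seed, group_by_patient = group_by_patient,
                mlp_widths = c(2304, 256, 128, 64, 32, 16, 1))
}

#' Stratified k-fold assignment
#'
#' Shuffled, label-stratified partition: within each class the shuffled
#' members are dealt into k nearly equal chunks, remainders going to the
#' currently smallest folds so fold sizes differ by at most one. With
#' `group_by_patient`, all maps of a patient share a fold and stratification
#' is best-effort at the patient level (patients stratified by whether they
#' contributed an optimal map majority).
#'
#' @param labels per-sample class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param group_by_patient logical.
#' @param patient_ids required when grouping.
#' @return integer vector of fold indices (1..k) per sample, with the seed in
#'   `attr(, "seed")`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1,
                             group_by_patient = FALSE, patient_ids = NULL) {
  n <- length(labels)
  stopifnot(k >= 2, n >= k)
  deal <- function(class_labels, k) {
    # shuffled within-class dealing; remainders go to the smallest folds
    out <- integer(length(class_labels))
    sizes <- integer(k)
    for (cl in unique(class_labels)) {
      idx <- sample(which(class_labels == cl))
      base <- length(idx) %/% k
      rem <- length(idx) %% k
      extra <- order(sizes, seq_len(k))[seq_len(rem)]
      counts <- rep(base, k)
      counts[extra] <- counts[extra] + 1
      out[idx] <- rep.int(seq_len(k), counts)
      sizes <- sizes + counts
    }
    out
  }
  if (group_by_patient) {
    stopifnot(!is.null(patient_ids), length(patient_ids) == n)
    pat <- unique(patient_ids)
    pat_label <- vapply(pat, function(p) round(mean(labels[patient_ids == p])),
                        0)
    pfold <- withr::with_seed(seed, deal(pat_label, k))
    folds <- pfold[match(patient_ids, pat)]
  } else {
    if (any(table(labels) < k)) {
      stop("every class needs at least k = ", k,
           " members for an ungrouped stratified split")
    }
    folds <- withr::with_seed(seed, deal(labels, k))
  }
  attr(folds, "seed") <- seed
  folds
}

#' Run the two-stage AE-MLP training with k-fold cross-validation
#'
#' Stage 1 trains the autoencoder on all nominal maps with the SSIM loss;
#' stage 2 freezes it, extracts the latent features once, and per fold trains
#' the optimal/non-optimal classifier (binary cross-entropy) and one
#' regressor per stimulation parameter (voltage, frequency, contact x/y/z;
#' MSE on z-scored targets), validating every epoch and keeping the
#' best-checkpoint weights. Out-of-fold predictions are pooled for
#' evaluation.
#'
#' @param dataset a [build_cohort_dataset()] result (or any list with
#'   `volumes`, `labels`, `targets`, `patient_id`).
#' @param plan a [training_plan()].
#' @param ae_config an [ae_config()] matching the volume shape.
#' @param verbose print stage progress.
#' @return object of class `folded_models`: the frozen `ae`, `folds`
#'   assignment, per-fold `classifiers` and `regressors` (5 targets x k
#'   folds), pooled out-of-fold predictions (`oof`), and per-fold `metrics`.
#' @export
run_algorithm1 <- function(dataset, plan = training_plan(),
                           ae_config = ae_config_desk(
                             input_shape = dim(dataset$volumes)[1:3]),
                           verbose = FALSE) {
  stopifnot(inherits(plan, "training_plan"))
  labels <- dataset$labels
  n <- length(labels)
  stopifnot(dim(dataset$volumes)[4] == n)
  seeds <- derive_seeds(plan$seed, 4 + plan$folds)

  if (verbose) message("stage 1: training autoencoder (", plan$ae_epochs,
                       " epochs, ", n, " maps)")
  ae <- ae_init(ae_config, seed = seeds[1])
  ae <- train_autoencoder(ae, dataset$volumes, epochs = plan$ae_epochs,
                          learning_rate = plan$ae_lr,
                          batch_size = plan$batch_size,
                          ssim_window = plan$ssim_window, seed = seeds[2],
                          verbose = verbose)

  ae_checksum_stage1 <- ae_weight_checksum(ae)
  Z <- ae_encode(ae, dataset$volumes)
  # column standardization of the latent features (an unsupervised transform
  # fitted, like the AE itself, on the full map set) conditions the MLP input
  scaling <- latent_scaling_from(Z)
  Zs <- scale_latent(Z, scaling)
  folds <- stratified_kfold(labels, plan$folds, seed = seeds[3],
                            group_by_patient = plan$group_by_patient,
                            patient_ids = dataset$patient_id)
  target_names <- colnames(dataset$targets)
  latent_dim <- ncol(Z)
  widths <- if (!is.null(plan$mlp_widths) &&
                plan$mlp_widths[1] == latent_dim) {
    plan$mlp_widths
  } else if (latent_dim == 2304) {
    mlp_config()$layer_widths
  } else {
    mlp_widths(latent_dim)
  }

  classifiers <- vector("list", plan$folds)
  regressors <- lapply(seq_len(plan$folds), function(i) {
    stats::setNames(vector("list", length(target_names)), target_names)
  })
  oof_prob <- rep(NA_real_, n)
  oof_pred <- matrix(NA_real_, n, length(target_names),
                     dimnames = list(NULL, target_names))
  metrics <- list()

  for (i in seq_len(plan$folds)) {
    tr <- which(folds != i)
    va <- which(folds == i)
    if (verbose) message("stage 2: fold ", i, " (", length(tr), " train / ",
                         length(va), " validation maps)")
    fold_seed <- seeds[4 + i]
    clf <- build_head(mlp_config(widths, head = "classifier"),
                      seed = fold_seed)
    clf <- train_head(clf, Zs[tr, , drop = FALSE], labels[tr],
                      Zs[va, , drop = FALSE], labels[va],
                      epochs = plan$mlp_epochs,
                      learning_rate = plan$mlp_lr,
                      batch_size = plan$batch_size, seed = fold_seed + 1)
    classifiers[[i]] <- clf
    oof_prob[va] <- classify_settings(clf, Zs[va, , drop = FALSE])$probability

    for (tn in target_names) {
      reg <- build_head(mlp_config(widths, head = "regressor"),
                        seed = fold_seed + match(tn, target_names))
      reg <- train_head(reg, Zs[tr, , drop = FALSE],
                        dataset$targets[[tn]][tr],
                        Zs[va, , drop = FALSE], dataset$targets[[tn]][va],
                        epochs = plan$mlp_epochs,
                        learning_rate = plan$mlp_lr,
                        batch_size = plan$batch_size,
                        seed = fold_seed + 10 + match(tn, target_names))
      regressors[[i]][[tn]] <- reg
      oof_pred[va, tn] <- predict_parameter(reg, Zs[va, , drop = FALSE])
    }

    cm <- classification_metrics(labels[va], oof_prob[va])
    metrics[[i]] <- data.frame(
      fold = i, accuracy = cm$accuracy, precision = cm$precision,
      recall = cm$recall, f1 = cm$f1,
      t(vapply(target_names, function(tn) {
        rmse(dataset$targets[[tn]][va], oof_pred[va, tn])
      }, 0) |> stats::setNames(paste0("rmse_", target_names))))
  }

  structure(list(
    ae = ae, folds = folds, classifiers = classifiers,
    regressors = regressors, latent = Z, latent_scaling = scaling,
    ae_checksum_stage1 = ae_checksum_stage1,
    oof = list(probability = oof_prob, predictions = oof_pred,
               labels = labels, targets = dataset$targets,
               patient_id = dataset$patient_id),
    metrics = do.call(rbind, metrics), plan = plan, seeds = seeds,
    target_names = target_names),
    class = "folded_models")
}

#' @export
print.folded_models <- function(x, ...) {
  cat("AE-MLP folded model set: ", length(x$classifiers), " folds, ",
      length(x$target_names), " regression targets\n", sep = "")
  cat("pooled out-of-fold accuracy: ",
      sprintf("%.3f", mean((x$oof$probability >= 0.5) == (x$oof$labels == 1))),
      "\n", sep = "")
  invisible(x)
}

#' Fold-ensemble classification probability
#'
#' Mean probability across the k fold classifiers (used by the closed loop,
#' where no fold assignment exists for a new map).
#'
#' @param models a `folded_models` object.
#' @param latent latent feature matrix.
#' @export
ensemble_probability <- function(models, latent) {
  latent <- scale_latent(latent, models$latent_scaling)
  p <- vapply(models$classifiers, function(clf) {
    classify_settings(clf, latent)$probability
  }, numeric(nrow(latent)))
  rowMeans(matrix(p, nrow = nrow(latent)))
}

#' Fold-ensemble parameter predictions
#'
#' @param models a `folded_models` object.
#' @param latent latent feature matrix.
#' @return matrix (rows = maps) of denormalized predictions per target.
#' @export
ensemble_predictions <- function(models, latent) {
  latent <- scale_latent(latent, models$latent_scaling)
  out <- vapply(models$target_names, function(tn) {
    p <- vapply(models$regressors, function(fold) {
      predict_parameter(fold[[tn]], latent)
    }, numeric(nrow(latent)))
    rowMeans(matrix(p, nrow = nrow(latent)))
  }, numeric(nrow(latent)))
  matrix(out, nrow = nrow(latent),
         dimnames = list(NULL, models$target_names))
}

# column standardization of latent features (constant columns pass through)
latent_scaling_from <- function(Z) {
  mu <- colMeans(Z)
  sdv <- apply(Z, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

scale_latent <- function(Z, scaling) {
  if (is.null(scaling)) return(Z)
  t((t(Z) - scaling$mean) / scaling$sd)
}

derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1, n))
}

#' Save / load a folded model set
#'
#' Serialised with R's native RDS container; the run manifest (plan, seeds,
#' fold assignment, metrics) is also written as JSON next to it.
#'
#' @param models a `folded_models` object.
#' @param path file path (`.rds`).
#' @export
save_folded_models <- function(models, path) {
  saveRDS(models, path)
  manifest <- list(plan = unclass(models$plan), seeds = models$seeds,
                   folds = as.integer(models$folds),
                   metrics = models$metrics)
  jsonlite::write_json(manifest, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_folded_models
#' @export
load_folded_models <- function(path) readRDS(path)
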