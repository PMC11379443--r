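# Performance metrics and diagnostics: classification metrics with pooled
# (fold-combined) ROC / precision-recall curves, regression RMSE and
# tolerance accuracy, cosine similarity index between latent feature sets,
# and the left-right-flip robustness report.

#' Classification metrics with ROC and precision-recall curves
#'
#' Confusion counts and derived rates at the decision threshold, plus full
#' threshold-sweep ROC and precision-recall curves with trapezoidal AUC.
#' Curves pool all supplied predictions; when predictions come from k-fold
#' validation sets this yields the fold-combined curves.
#'
#' @param labels 0/1 (or logical) ground-truth labels.
#' @param probabilities predicted probabilities of the positive class.
#' @param threshold decision threshold (`>=` is positive).
#' @return list of class `classification_report`: `tp`, `fp`, `fn`, `tn`,
#'   `accuracy`, `precision`, `recall`, `f1`, and (when both classes are
#'   present) `roc` / `pr` curve data frames with `roc_auc` / `pr_auc`.
#' @export
classification_metrics <- function(labels, probabilities, threshold = 0.5) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0, 1)))
  pred <- as.numeric(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              accuracy = (tp + tn) / length(labels),
              precision = precision, recall = recall, f1 = f1,
              threshold = threshold)
  if (length(unique(labels)) < 2) {
    out$curves_skipped <- "both classes are required for ROC/PR curves"
  } else {
    cuts <- c(Inf, sort(unique(probabilities), decreasing = TRUE), -Inf)
    sweep_counts <- vapply(cuts, function(ct) {
      p <- probabilities >= ct
      c(tpr = sum(p & labels == 1) / sum(labels == 1),
        fpr = sum(p & labels == 0) / sum(labels == 0),
        prec = if (any(p)) sum(p & labels == 1) / sum(p) else 1)
    }, numeric(3))
    roc <- data.frame(threshold = cuts, fpr = sweep_counts["fpr", ],
                      tpr = sweep_counts["tpr", ])
    out$roc <- roc
    out$roc_auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                          utils::tail(roc$tpr, -1)) / 2)
    pr <- data.frame(threshold = cuts, recall = sweep_counts["tpr", ],
                     precision = sweep_counts["prec", ])
    out$pr <- pr
    out$pr_auc <- sum(diff(pr$recall) * (utils::head(pr$precision, -1) +
                                           utils::tail(pr$precision, -1)) / 2)
  }
  structure(out, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f",
              x$accuracy, x$precision, x$recall, x$f1))
  if (!is.null(x$roc_auc)) {
    cat(sprintf("  ROC AUC %.3f  PR AUC %.3f", x$roc_auc, x$pr_auc))
  }
  cat("\n")
  invisible(x)
}

#' Fold-wise mean and standard deviation of metrics
#'
#' @param metrics per-fold metric data frame (as in `folded_models$metrics`).
#' @return data frame with one row per metric: mean and sd across folds.
#' @export
summarize_fold_metrics <- function(metrics) {
  num <- metrics[, setdiff(colnames(metrics), "fold"), drop = FALSE]
  data.frame(metric = colnames(num),
             mean = vapply(num, mean, 0),
             sd = vapply(num, stats::sd, 0), row.names = NULL)
}

#' Root mean square error
#'
#' @param y_true,y_pred numeric vectors of equal nonzero length.
#' @return `sqrt(mean((y_true - y_pred)^2))` in target units.
#' @export
rmse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  sqrt(mean((y_true - y_pred)^2))
}

#' Tolerance accuracy of predictions
#'
#' Fraction of predictions within `tol_fraction` relative deviation of the
#' ground truth: `|pred - true| <= tol_fraction * |true|`. A zero-valued
#' truth counts as accurate only for an exactly zero prediction (the relative
#' criterion is undefined there).
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @param tol_fraction relative tolerance (e.g. 0.10, 0.15).
#' @return fraction in `[0, 1]`.
#' @export
tolerance_accuracy <- function(y_true, y_pred, tol_fraction) {
  stopifnot(length(y_true) == length(y_pred), tol_fraction >= 0)
  ok <- ifelse(y_true == 0, y_pred == 0,
               abs(y_pred - y_true) <= tol_fraction * abs(y_true))
  mean(ok)
}

#' Cosine similarity index between two latent feature sets
#'
#' `paired_mean`: mean over rows of the cosine between matched feature
#' vectors (the headline statistic). `group_mean`: cosine between the two
#' group-mean vectors. Zero-norm vectors yield `NA` with a warning.
#'
#' @param features_a,features_b matrices with matched rows/columns.
#' @param mode `"paired-mean"` or `"group-mean"`.
#' @return scalar in `[-1, 1]` (or `NA`).
#' @export
cosine_similarity_index <- function(features_a, features_b,
                                    mode = c("paired-mean", "group-mean")) {
  mode <- match.arg(mode)
  features_a <- rbind(features_a)
  features_b <- rbind(features_b)
  stopifnot(identical(dim(features_a), dim(features_b)))
  cosine <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) {
      warning("zero-norm feature vector; cosine undefined")
      return(NA_real_)
    }
    sum(u * v) / (nu * nv)
  }
  if (mode == "paired-mean") {
    mean(vapply(seq_len(nrow(features_a)), function(i) {
      cosine(features_a[i, ], features_b[i, ])
    }, 0))
  } else {
    cosine(colMeans(features_a), colMeans(features_b))
  }
}

#' Permutation baseline for the cosine similarity index
#'
#' Mean cosine between randomly mismatched row pairs of the two feature sets,
#' averaged over shuffles; the reference level against which a paired CSI is
#' judged.
#'
#' @inheritParams cosine_similarity_index
#' @param n_shuffles number of random pairings.
#' @param seed RNG seed.
#' @return mean mismatched-pair cosine.
#' @export
csi_permutation_baseline <- function(features_a, features_b,
                                     n_shuffles = 1000, seed = 1) {
  n <- nrow(features_a)
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_shuffles), function(s) {
      perm <- sample.int(n)
      # derangement-ish: resample rows that map to themselves
      fix <- which(perm == seq_len(n))
      if (length(fix) > 1) perm[fix] <- perm[sample(fix)]
      cosine_similarity_index(features_a, features_b[perm, , drop = FALSE])
    }, 0))
  })
}

#' Left-right-flip robustness report
#'
#' Flips every volume along the left-right axis, extracts latent features for
#' the nominal and flipped sets with the same frozen autoencoder, and
#' summarises their agreement per label group: paired-mean and group-mean
#' cosine similarity, the permutation baseline, and violin summary statistics
#' (quartiles) of the latent value distributions.
#'
#' @param ae a trained `dbs_ae`.
#' @param volumes 4-d array of preprocessed nominal maps.
#' @param labels 0/1 optimal labels per map.
#' @param n_shuffles shuffles for the permutation baseline.
#' @param seed RNG seed for the baseline.
#' @return list of class `flip_report` with per-group CSI values, baselines,
#'   violin statistics, and the two latent matrices.
#' @export
flip_robustness_report <- function(ae, volumes, labels, n_shuffles = 1000,
                                   seed = 1) {
  stopifnot(length(dim(volumes)) == 4, dim(volumes)[4] == length(labels))
  flipped <- volumes[rev(seq_len(dim(volumes)[1])), , , , drop = FALSE]
  z_nom <- ae_encode(ae, volumes)
  z_flip <- ae_encode(ae, flipped)
  groups <- list(optimal = which(labels == 1),
                 non_optimal = which(labels == 0))
  per_group <- lapply(groups, function(idx) {
    a <- z_nom[idx, , drop = FALSE]
    b <- z_flip[idx, , drop = FALSE]
    list(csi_paired = cosine_similarity_index(a, b, "paired-mean"),
         csi_group = cosine_similarity_index(a, b, "group-mean"),
         baseline = if (length(idx) > 2) {
           csi_permutation_baseline(a, b, n_shuffles, seed)
         } else NA_real_,
         violin = data.frame(
           set = c("nominal", "flipped"),
           rbind(stats::quantile(a, c(0.25, 0.5, 0.75)) |>
                   stats::setNames(c("q25", "median", "q75")),
                 stats::quantile(b, c(0.25, 0.5, 0.75)) |>
                   stats::setNames(c("q25", "median", "q75")))))
  })
  structure(list(groups = per_group, latent_nominal = z_nom,
                 latent_flipped = z_flip, labels = labels),
            class = "flip_report")
}

#' @export
print.flip_report <- function(x, ...) {
  for (g in names(x$groups)) {
    cat(sprintf("%-12s CSI (paired) %.3f  (group) %.3f  baseline %.3f\n",
                g, x$groups[[g]]$csi_paired, x$groups[[g]]$csi_group,
                x$groups[[g]]$baseline))
  }
  invisible(x)
}

#' Prediction report for one regression target
#'
#' @param y_true,y_pred vectors in physical units.
#' @param tolerances relative tolerances to report accuracy at.
#' @return list with `rmse` and `tolerance_accuracy` (named by tolerance).
#' @export
prediction_report <- function(y_true, y_pred, tolerances = c(0.10, 0.15)) {
  list(rmse = rmse(y_true, y_pred),
       tolerance_accuracy = stats::setNames(
         vapply(tolerances, function(tl) tolerance_accuracy(y_true, y_pred,
                                                            tl), 0),
         paste0("tol_", tolerances * 100, "pct")))
}
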