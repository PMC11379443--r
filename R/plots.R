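# Optional ggplot2 visualisations of evaluation output. ggplot2 is a
# suggested dependency; each function checks for it at call time.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; install it or use the raw ",
         "curve/report data directly")
  }
}

#' Plot pooled ROC and precision-recall curves
#'
#' @param report a [classification_metrics()] result with curves.
#' @param which `"roc"` or `"pr"`.
#' @return a ggplot object.
#' @export
plot_curves <- function(report, which = c("roc", "pr")) {
  need_ggplot()
  which <- match.arg(which)
  if (is.null(report$roc)) stop(report$curves_skipped)
  if (which == "roc") {
    ggplot2::ggplot(report$roc, ggplot2::aes(x = fpr, y = tpr)) +
      ggplot2::geom_path() +
      ggplot2::geom_abline(linetype = 3) +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
                    title = sprintf("ROC (AUC = %.3f)", report$roc_auc))
  } else {
    ggplot2::ggplot(report$pr, ggplot2::aes(x = recall, y = precision)) +
      ggplot2::geom_path() +
      ggplot2::labs(x = "recall", y = "precision",
                    title = sprintf("Precision-recall (AUC = %.3f)",
                                    report$pr_auc))
  }
}

#' Violin plot of latent feature distributions, nominal vs flipped
#'
#' @param report a [flip_robustness_report()] result.
#' @param group `"optimal"` or `"non_optimal"`.
#' @return a ggplot object.
#' @export
plot_flip_violin <- function(report, group = c("optimal", "non_optimal")) {
  need_ggplot()
  group <- match.arg(group)
  idx <- which(report$labels == (group == "optimal"))
  df <- rbind(
    data.frame(set = "nominal",
               value = as.numeric(report$latent_nominal[idx, ])),
    data.frame(set = "flipped",
               value = as.numeric(report$latent_flipped[idx, ])))
  ggplot2::ggplot(df, ggplot2::aes(x = set, y = value)) +
    ggplot2::geom_violin() +
    ggplot2::labs(title = sprintf("%s maps: CSI (paired) = %.3f", group,
                                  report$groups[[group]]$csi_paired),
                  x = NULL, y = "latent feature value")
}

#' Scatter plot of predicted vs target parameter values
#'
#' With the identity line, a linear fit and its confidence band.
#'
#' @param y_true,y_pred vectors in physical units.
#' @param target_name axis label (e.g. "voltage (V)").
#' @return a ggplot object.
#' @export
plot_prediction_scatter <- function(y_true, y_pred, target_name = "target") {
  need_ggplot()
  df <- data.frame(truth = y_true, prediction = y_pred)
  ggplot2::ggplot(df, ggplot2::aes(x = truth, y = prediction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
    ggplot2::labs(x = paste("target", target_name),
                  y = paste("predicted", target_name))
}

#' Plot a t-SNE embedding coloured by label
#'
#' @param embedding a [tsne_embed()] result carrying a `label` column.
#' @return a ggplot object.
#' @export
plot_tsne <- function(embedding) {
  need_ggplot()
  stopifnot(!is.null(embedding$label))
  ggplot2::ggplot(embedding,
                  ggplot2::aes(x = x, y = y,
                               colour = factor(label))) +
    ggplot2::geom_point() +
    ggplot2::labs(colour = "label", x = "t-SNE 1", y = "t-SNE 2")
}

#' Plot an autoencoder training-loss trace
#'
#' @param ae a trained `dbs_ae`.
#' @return a ggplot object.
#' @export
plot_loss_trace <- function(ae) {
  need_ggplot()
  df <- data.frame(epoch = seq_along(ae$loss_trace), loss = ae$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "reconstruction loss (1 - SSIM)")
}
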