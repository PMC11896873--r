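# ggplot2 visualizations for evaluation results and screening profiles.

#' Plot a ROC or PR curve
#'
#' @param curve Curve tibble from [roc_curve_auc()] (`fpr`/`tpr`) or
#'   [pr_curve_auc()] (`recall`/`precision`).
#' @param auc Optional AUC to show in the subtitle.
#' @return A ggplot object.
#' @export
plot_curve <- function(curve, auc = NULL) {
  stopifnot(is.data.frame(curve))
  sub <- if (!is.null(auc)) sprintf("AUC = %.3f", auc) else NULL
  if (all(c("fpr", "tpr") %in% names(curve))) {
    ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           color = "grey60") +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = "ROC curve", subtitle = sub) +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = "Precision-recall curve", subtitle = sub) +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::theme_minimal()
  }
}

#' @describeIn cross_validate Per-fold metric dot plot with cross-fold mean.
#' @param object A `dmpnn_cv`.
#' @export
autoplot.dmpnn_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds[, c("fold", "sensitivity", "specificity",
                     "balanced_accuracy", "mcc", "roc_auc", "pr_auc")],
    -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$fold)), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Value", color = "Fold",
                  title = sprintf("%d-fold cross-validation", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heatmap of a screening profile
#'
#' Compounds by (target, mode) call matrix; out-of-domain cells are struck
#' through when `mask_ad` is set.
#'
#' @param object A `screening_profile` from [profile_batch()].
#' @param mask_ad Grey out cells outside the applicability domain.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screening_profile <- function(object, mask_ad = TRUE, ...) {
  df <- as_tibble(object)
  df$cell <- df$call
  if (mask_ad) df$cell[!is.na(df$in_domain) & !df$in_domain] <- "out_of_domain"
  df$cell[is.na(df$cell)] <- "rejected"
  ggplot2::ggplot(df, ggplot2::aes(x = paste(.data$target, .data$mode),
                                   y = .data$record_id,
                                   fill = .data$cell)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(
      active = "#c0392b", inactive = "#27ae60",
      out_of_domain = "grey75", rejected = "grey40")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
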