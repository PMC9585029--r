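# ggplot2 displays of the result objects.

#' @describeIn five_fold_cv ROC and precision-recall curves per fold.
#' @param object An `hgnnlda_cv`.
#' @export
autoplot.hgnnlda_cv <- function(object, ...) {
  curves <- object$scores |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(function(df, key) {
      mr <- compute_metrics(df$score, df$label)
      dplyr::bind_rows(
        dplyr::mutate(mr$roc, panel = "ROC", x = .data$fpr, y = .data$tpr),
        dplyr::mutate(mr$pr, panel = "Precision-recall",
                      x = .data$recall, y = .data$precision)
      )
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$x, .data$y,
                               colour = factor(.data$fold))) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(
      x = NULL, y = NULL, colour = "fold",
      title = sprintf("Cross-validation (mean AUC %.3f, mean AUPR %.3f)",
                      object$mean_auc, object$mean_aupr)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_hgnnlda Training loss trajectory plot.
#' @param object An `hgnnlda_fit`.
#' @param ... Unused.
#' @export
autoplot.hgnnlda_fit <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy",
                  title = sprintf("Training loss (%s, d = %d)",
                                  object$variant, object$config$d)) +
    ggplot2::theme_minimal()
}

#' @describeIn embedding_size_sweep Mean AUC against embedding size.
#' @param object An `hgnnlda_sweep` tibble.
#' @param ... Unused.
#' @export
autoplot.hgnnlda_sweep <- function(object, ...) {
  summ <- object |>
    dplyr::group_by(.data$d) |>
    dplyr::summarise(mean_auc = mean(.data$mean_auc), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$d, .data$mean_auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object,
                        ggplot2::aes(.data$d, .data$mean_auc),
                        alpha = 0.5) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "embedding size d", y = "mean AUC") +
    ggplot2::theme_minimal()
}

#' @describeIn run_ablation Mean AUC per model variant.
#' @param object An `hgnnlda_ablation` tibble.
#' @param ... Unused.
#' @export
autoplot.hgnnlda_ablation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$variant, .data$mean_auc)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "mean AUC") +
    ggplot2::theme_minimal()
}
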