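# ggplot2 visualizations for the result types.

#' @export
autoplot.gnn_metrics <- function(object, ...) {
  roc_df <- imap(object$roc, function(r, cl) mutate(r, class = cl)) |>
    bind_rows()
  if (nrow(roc_df) == 0L) {
    abort("no ROC curves available (single-class test set)",
      class = "generisk_config_error"
    )
  }
  ggplot2::ggplot(roc_df, ggplot2::aes(x = .data$fpr, y = .data$tpr, color = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste0(object$family, " - ", object$task),
      subtitle = sprintf("accuracy %.2f%%, F1 %.3f", object$accuracy, object$f1),
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.embedding_projection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y, color = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gnn_fit <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss_trace), loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = paste0(object$spec$family, " training loss (", object$task, ")"),
      y = "NLL loss"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pipeline_run <- function(object, ...) {
  ggplot2::ggplot(
    object$comparison,
    ggplot2::aes(x = stats::reorder(.data$model, .data$accuracy), y = .data$accuracy)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Test accuracy (%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.model_ordering_study <- function(object, ...) {
  ggplot2::ggplot(
    object$accuracy,
    ggplot2::aes(x = .data$variant, y = .data$accuracy)
  ) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Test accuracy (%) across seeds") +
    ggplot2::theme_minimal()
}
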