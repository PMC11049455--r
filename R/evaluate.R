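# Evaluation: per-class specificity/sensitivity (one-vs-rest), accuracy,
# F1, confusion matrix, per-class ROC curves with Youden-optimal thresholds,
# and top-confidence gene rankings.

#' Per-class rates from a confusion matrix
#'
#' Rows are truth, columns are predictions. For each class (one-vs-rest):
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), F1 = harmonic mean of precision and sensitivity. Classes
#' absent from the truth get `NA` rates (undefined, not zero). Accuracy is
#' `100 * trace / total`.
#'
#' @param cm Square numeric matrix (truth x predicted) with matching
#'   dimnames, or an unnamed square matrix.
#' @return A list with `per_class` (tibble), `accuracy` (percent),
#'   `f1_macro`, and the matrix itself.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) {
    abort("confusion matrix must be square", class = "generisk_config_error")
  }
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  total <- sum(cm)
  per_class <- map(seq_along(classes), function(ci) {
    tp <- cm[ci, ci]
    fn <- sum(cm[ci, ]) - tp
    fp <- sum(cm[, ci]) - tp
    tn <- total - tp - fn - fp
    sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
      NA_real_
    } else {
      2 * prec * sens / (prec + sens)
    }
    tibble(
      class = classes[ci], n_truth = tp + fn,
      sensitivity = sens, specificity = spec, precision = prec, f1 = f1
    )
  }) |> bind_rows()
  list(
    per_class = per_class,
    accuracy = 100 * sum(diag(cm)) / total,
    f1_macro = mean(per_class$f1[per_class$n_truth > 0]),
    confusion = cm
  )
}

# The positive class of the two binary tasks (second factor level).
positive_class <- function(classes) {
  if (length(classes) == 2L) classes[2L] else NA_character_
}

#' Build a ROC curve from scores
#'
#' Sweeps every observed score as a cutoff (predict positive when
#' `score >= threshold`); the curve starts at (0, 0) and ends at (1, 1)
#' with nondecreasing false-positive rate.
#'
#' @param scores Numeric confidences for the positive class.
#' @param truth Logical (or 2-level factor, second level positive) truth.
#' @return A tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve_points <- function(scores, truth) {
  truth <- as_positive_logical(truth)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  np <- sum(truth)
  nn <- sum(!truth)
  # collapse tied scores into single cut points
  cum_tp <- cumsum(t)
  cum_fp <- cumsum(!t)
  last_of_tie <- c(diff(s) != 0, TRUE)
  tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, cum_fp[last_of_tie] / max(nn, 1L)),
    tpr = c(0, cum_tp[last_of_tie] / max(np, 1L))
  )
}

as_positive_logical <- function(truth) {
  if (is.logical(truth)) {
    return(truth)
  }
  if (is.factor(truth)) {
    return(truth == levels(truth)[2L])
  }
  if (is.numeric(truth)) {
    return(truth != 0)
  }
  abort("truth must be logical, numeric, or a 2-level factor",
    class = "generisk_config_error"
  )
}

auc_trapezoid <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Rank-statistic (concordance) formulation of the AUC, with ties counted 1/2.
auc_concordance <- function(scores, truth) {
  truth <- as_positive_logical(truth)
  np <- sum(truth)
  nn <- sum(!truth)
  r <- rank(scores)
  (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}

#' Youden-optimal classification threshold from a ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over all score
#' cutoffs; ties are broken toward higher specificity.
#'
#' @inheritParams roc_curve_points
#' @return A list: `threshold`, `sensitivity`, `specificity`, `j`, `auc`,
#'   and the `roc` tibble.
#' @export
roc_optimal_threshold <- function(scores, truth) {
  truth <- as_positive_logical(truth)
  if (length(unique(truth)) < 2L) {
    abort("both classes must be present to build a ROC curve",
      class = "generisk_config_error"
    )
  }
  roc <- roc_curve_points(scores, truth)
  j <- roc$tpr - roc$fpr
  best_j <- max(j)
  candidates <- which(j >= best_j - 1e-12)
  best <- candidates[which.min(roc$fpr[candidates])]
  list(
    threshold = roc$threshold[best],
    sensitivity = roc$tpr[best],
    specificity = 1 - roc$fpr[best],
    j = j[best],
    auc = auc_trapezoid(roc$fpr, roc$tpr),
    roc = roc
  )
}

#' Evaluate a fitted classifier on test nodes
#'
#' Computes the full metrics report on the given test indices: confusion
#' matrix, per-class specificity and sensitivity (one-vs-rest), accuracy in
#' percent, F1 (positive-class F1 for the two binary tasks, macro F1 for
#' multi-class; both are reported), and one-vs-rest ROC curves with AUC per
#' class. For binary tasks the Youden-optimal threshold on the positive
#' class is included.
#'
#' @param fit A `gnn_fit`.
#' @param graph The graph the test indices refer to.
#' @param test_idx Integer test-node indices.
#' @param originals_only Drop upsampled duplicates from the test set before
#'   scoring.
#' @return A `gnn_metrics` object.
#' @export
evaluate <- function(fit, graph, test_idx, originals_only = FALSE) {
  if (originals_only) {
    test_idx <- intersect(test_idx, which(is_original_node(graph)))
  }
  if (length(test_idx) == 0L) {
    abort("test set is empty", class = "generisk_config_error")
  }
  labels <- graph$labels[[fit$task]]
  logp <- forward(fit, graph)
  probs <- exp(logp)
  pred <- factor(fit$classes[max.col(probs)], levels = fit$classes)

  truth <- labels[test_idx]
  cm <- table(truth = truth, predicted = pred[test_idx])
  base <- metrics_from_confusion(unclass(cm))

  roc_by_class <- list()
  auc_by_class <- numeric(0)
  for (cl in fit$classes) {
    is_cl <- truth == cl
    if (length(unique(is_cl)) < 2L) next
    roc <- roc_curve_points(probs[test_idx, cl], is_cl)
    roc_by_class[[cl]] <- roc
    auc_by_class[cl] <- auc_trapezoid(roc$fpr, roc$tpr)
  }

  pos <- positive_class(fit$classes)
  optimal <- NULL
  if (!is.na(pos) && length(unique(truth == pos)) == 2L) {
    optimal <- roc_optimal_threshold(probs[test_idx, pos], truth == pos)
  }
  f1 <- if (!is.na(pos)) {
    base$per_class$f1[base$per_class$class == pos]
  } else {
    base$f1_macro
  }

  structure(
    list(
      task = fit$task, family = fit$spec$family,
      featureless = fit$spec$featureless,
      classes = fit$classes,
      confusion = base$confusion,
      per_class = base$per_class,
      accuracy = base$accuracy,
      f1 = f1, f1_macro = base$f1_macro,
      roc = roc_by_class, auc = auc_by_class,
      optimal_threshold = optimal,
      n_test = length(test_idx)
    ),
    class = "gnn_metrics"
  )
}

#' @exportS3Method base::print
print.gnn_metrics <- function(x, ...) {
  cat(
    "<gnn_metrics>", x$family, "on", x$task, "-",
    "accuracy", sprintf("%.2f%%", x$accuracy),
    "F1", sprintf("%.3f", x$f1), "(n test =", x$n_test, ")\n"
  )
  print(as.data.frame(x$per_class), digits = 3)
  invisible(x)
}

#' @export
tidy.gnn_metrics <- function(x, ...) {
  x$per_class |>
    mutate(
      auc = unname(x$auc[.data$class]),
      task = x$task, family = x$family, .before = 1L
    )
}

#' @export
glance.gnn_metrics <- function(x, ...) {
  tibble(
    task = x$task, family = x$family, featureless = x$featureless,
    accuracy = x$accuracy, f1 = x$f1, f1_macro = x$f1_macro,
    n_test = x$n_test,
    auc = if (length(x$auc)) mean(x$auc) else NA_real_
  )
}

#' Highest-confidence genes for a class
#'
#' Ranks the original (non-duplicate) nodes that the model predicts as the
#' given class by their softmax confidence for that class, descending, and
#' returns the top `k`.
#'
#' @param fit A `gnn_fit`.
#' @param graph Graph to score.
#' @param class Class name.
#' @param k List length (a shorter list is returned, with a warning, when
#'   fewer nodes qualify).
#' @return A tibble with `rank`, `symbol`, `confidence`.
#' @export
top_confidence_genes <- function(fit, graph, class, k = 10L) {
  if (!class %in% fit$classes) {
    abort(paste0("unknown class '", class, "'"), class = "generisk_config_error")
  }
  probs <- exp(forward(fit, graph))
  pred <- fit$classes[max.col(probs)]
  eligible <- which(pred == class & is_original_node(graph))
  if (length(eligible) < k) {
    warn(paste0(
      "only ", length(eligible), " genes predicted as '", class,
      "'; returning a shorter list"
    ))
  }
  take <- eligible[order(probs[eligible, class], decreasing = TRUE)]
  take <- head(take, k)
  tibble(
    rank = seq_along(take),
    symbol = graph$nodes[take],
    confidence = probs[take, class]
  )
}
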