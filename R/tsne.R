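# Exact t-distributed stochastic neighbor embedding for visualizing learned
# node representations. O(n^2) per iteration, intended for the cohort sizes
# this package targets (a few thousand nodes at most).

# Per-point precision calibration: binary search beta so the conditional
# distribution's perplexity matches the target.
tsne_affinities <- function(x, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    beta_lo <- -Inf
    beta_hi <- Inf
    for (it in seq_len(max_tries)) {
      w <- exp(-d2[i, ] * beta)
      sw <- sum(w)
      if (sw <= 0) {
        h <- 0
      } else {
        pi_ <- w / sw
        h <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    p[i, ] <- w / max(sum(w), .Machine$double.eps)
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

tsne_exact <- function(x, perplexity = 30, seed = 1L, max_iter = 400L,
                       learning_rate = 200, initial_dims = 50L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (ncol(x) > initial_dims) {
    x <- prcomp(x, rank. = initial_dims, center = TRUE, scale. = FALSE)$x
  }
  p <- tsne_affinities(x, perplexity)
  set.seed(seed)
  y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exaggeration <- 4
  for (iter in seq_len(max_iter)) {
    pe <- if (iter <= 100L) p * exaggeration else p
    sq <- rowSums(y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(y))
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (pe - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    momentum <- if (iter < 250L) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - learning_rate * gains * grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))
  }
  y
}

#' Project learned node embeddings to 2-D with t-SNE
#'
#' Runs a seeded exact t-SNE on the chosen embedding layer (default: the
#' penultimate representation feeding the classifier head) so classes can
#' be inspected visually while preserving local structure.
#'
#' @param fit A `gnn_fit`.
#' @param graph Graph to embed.
#' @param nodes Optional integer subset of nodes to project (default all).
#' @param layer `"penultimate"` (learned representation) or `"input"`
#'   (raw features).
#' @param seed Seed for the projection initialization.
#' @param perplexity t-SNE perplexity; requires at least `3 * perplexity`
#'   points.
#' @param max_iter Gradient-descent iterations.
#' @return An `embedding_projection` tibble: `symbol`, `x`, `y`, `class`.
#' @export
project_embeddings <- function(fit, graph, nodes = NULL,
                               layer = c("penultimate", "input"),
                               seed = 1L, perplexity = 30, max_iter = 400L) {
  layer <- match.arg(layer)
  nodes <- nodes %||% seq_len(n_nodes(graph))
  if (length(nodes) < 3 * perplexity) {
    abort(
      paste0(
        "t-SNE needs at least 3 * perplexity = ", ceiling(3 * perplexity),
        " points but got ", length(nodes),
        "; lower `perplexity` or project more nodes"
      ),
      class = "generisk_config_error"
    )
  }
  emb <- if (layer == "penultimate") {
    model_embeddings(fit, graph)[nodes, , drop = FALSE]
  } else {
    as.matrix(graph$features[nodes, , drop = FALSE])
  }
  coords <- tsne_exact(emb, perplexity = perplexity, seed = seed, max_iter = max_iter)
  out <- tibble(
    symbol = graph$nodes[nodes],
    x = coords[, 1L],
    y = coords[, 2L],
    class = graph$labels[[fit$task]][nodes]
  )
  structure(out,
    class = c("embedding_projection", class(out)),
    seed = seed, perplexity = perplexity, layer = layer
  )
}
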