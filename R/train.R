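# Training: negative log-likelihood on log-softmax outputs, AdamW updates,
# full-graph passes for the message-passing families and minibatches for the
# MLP baseline.

#' Training configuration
#'
#' Defaults follow the study regimen: learning rate 0.001, weight decay
#' 5e-4, AdamW with numerical-stability epsilon 1e-4, batch size 64, 5000
#' epochs, log-softmax outputs with negative log-likelihood loss. Graph
#' families train full-batch (message passing needs the whole graph), so
#' `batch_size` applies to the MLP family only.
#'
#' @param learning_rate AdamW step size.
#' @param weight_decay Decoupled weight decay.
#' @param epsilon AdamW numerical-stability epsilon.
#' @param batch_size Minibatch size (MLP family).
#' @param epochs Training epochs.
#' @param beta1,beta2 AdamW moment decay rates.
#' @param seed Seed for initialization, random attention features, and
#'   minibatch shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.001,
                         weight_decay = 5e-4,
                         epsilon = 1e-4,
                         batch_size = 64L,
                         epochs = 5000L,
                         beta1 = 0.9,
                         beta2 = 0.999,
                         seed = 1L) {
  if (learning_rate < 0 || weight_decay < 0 || epochs < 1 || batch_size < 1) {
    abort("training rates must be nonnegative and epochs/batch_size positive",
      class = "generisk_config_error"
    )
  }
  structure(
    list(
      learning_rate = learning_rate, weight_decay = weight_decay,
      epsilon = epsilon, batch_size = as.integer(batch_size),
      epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

adamw_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adamw_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1
  b2 <- cfg$beta2
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    step <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + cfg$epsilon)
    params[[nm]] <- params[[nm]] - cfg$learning_rate * step -
      cfg$learning_rate * cfg$weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

#' Train a node classifier
#'
#' Optimizes the negative log-likelihood of the training nodes' labels with
#' AdamW. Graph families (`gcn`, `sage`, `transformer`) use full-graph
#' forward passes with the loss restricted to the training indices; the
#' `mlp` family trains on shuffled minibatches of its training rows. The
#' run is deterministic for a fixed `config$seed`, and the per-epoch loss
#' trace is recorded.
#'
#' @param spec A [model_spec()].
#' @param graph A `gene_graph` or `balanced_graph`.
#' @param task Which label set to fit.
#' @param train_idx Integer indices of training nodes.
#' @param config A [train_config()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation of the same updates; the two agree to numerical
#'   precision).
#' @return A `gnn_fit` with the learned parameters, class levels, the loss
#'   trace, and everything needed for prediction.
#' @export
train <- function(spec, graph, task, train_idx, config = train_config(),
                  engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (length(train_idx) == 0L) {
    abort("train_idx is empty", class = "generisk_config_error")
  }
  labels <- graph$labels[[task]]
  if (is.null(labels)) {
    abort(paste0("graph has no labels for task '", task, "'"),
      class = "generisk_config_error"
    )
  }
  x <- model_features(spec, graph)
  y <- as.integer(labels)
  n_classes <- nlevels(labels)
  ops <- model_operators(spec, graph)
  # first-layer aggregate is constant across epochs; precompute it
  if (spec$family == "gcn") {
    ops$m1 <- ops$adj %*% x
  } else if (spec$family == "sage") {
    ops$m1 <- cbind2(x, ops$adj %*% x)
  }

  init <- init_model(spec, ncol(x), n_classes, derive_seed(config$seed, "init"))
  params <- init$params
  fixed <- init$fixed

  if (engine == "cpp") {
    res <- train_engine_cpp(spec, params, fixed, x, ops, y, train_idx, config)
    params <- res$params
    trace <- res$trace
    bad <- which(!is.finite(trace))
    if (length(bad) > 0L) {
      abort(paste0("non-finite loss at epoch ", bad[1L]),
        class = "generisk_numeric_error"
      )
    }
    return(new_gnn_fit(spec, params, fixed, task, labels, config, trace, graph, x))
  }

  state <- adamw_init(params)
  trace <- numeric(config$epochs)

  if (spec$family == "mlp") {
    x_dense <- as.matrix(x)
    set.seed(derive_seed(config$seed, "train"))
    for (epoch in seq_len(config$epochs)) {
      idx <- train_idx[sample.int(length(train_idx))]
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        lg <- loss_and_grad(
          spec, params, fixed, x_dense[b, , drop = FALSE],
          ops, y[b], seq_along(b)
        )
        losses[bi] <- lg$loss * length(b)
        upd <- adamw_step(params, lg$grads, state, config)
        params <- upd$params
        state <- upd$state
      }
      trace[epoch] <- sum(losses) / length(idx)
      if (!is.finite(trace[epoch])) {
        abort(paste0("non-finite loss at epoch ", epoch),
          class = "generisk_numeric_error"
        )
      }
    }
  } else {
    for (epoch in seq_len(config$epochs)) {
      lg <- loss_and_grad(spec, params, fixed, x, ops, y, train_idx)
      trace[epoch] <- lg$loss
      if (!is.finite(lg$loss)) {
        abort(paste0("non-finite loss at epoch ", epoch),
          class = "generisk_numeric_error"
        )
      }
      upd <- adamw_step(params, lg$grads, state, config)
      params <- upd$params
      state <- upd$state
    }
  }

  new_gnn_fit(spec, params, fixed, task, labels, config, trace, graph, x)
}

new_gnn_fit <- function(spec, params, fixed, task, labels, config, trace,
                        graph, x) {
  structure(
    list(
      spec = spec, params = params, fixed = fixed,
      task = task, classes = levels(labels),
      config = config, loss_trace = trace,
      n_nodes = n_nodes(graph), in_dim = ncol(x)
    ),
    class = "gnn_fit"
  )
}

# Bridge to the compiled engine: biases travel as 1-row matrices, the MLP's
# per-epoch minibatch shuffles are drawn R-side so both engines share the
# same RNG stream.
train_engine_cpp <- function(spec, params, fixed, x, ops, y, train_idx, config) {
  packed <- lapply(params, function(p) if (is.matrix(p)) p else matrix(p, nrow = 1L))
  empty_sp <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(0L, 0L))
  empty_m <- matrix(0, 0L, 0L)
  y0 <- as.integer(y) - 1L

  if (spec$family == "mlp") {
    x_dense <- as.matrix(x)
    set.seed(derive_seed(config$seed, "train"))
    order <- vapply(
      seq_len(config$epochs),
      function(e) train_idx[sample.int(length(train_idx))] - 1L,
      integer(length(train_idx))
    )
    res <- cpp_train_mlp(
      x_dense, packed, y0, order, config$batch_size,
      config$learning_rate, config$weight_decay, config$epsilon,
      config$beta1, config$beta2
    )
  } else {
    family_code <- match(spec$family, c("gcn", "sage", "transformer"))
    as_dgc <- function(m) as(as(m, "generalMatrix"), "CsparseMatrix")
    res <- cpp_train_graph(
      family_code,
      if (spec$family == "transformer") as_dgc(x) else empty_sp,
      if (is.null(ops$m1)) empty_sp else as_dgc(ops$m1),
      if (is.null(ops$adj)) empty_sp else as_dgc(ops$adj),
      if (is.null(ops$adj_t)) empty_sp else as_dgc(ops$adj_t),
      packed,
      fixed$wf1 %||% empty_m, fixed$wf2 %||% empty_m,
      spec$attention == "kernelized", spec$phi == "exp_random",
      isTRUE(spec$qk_norm), spec$temperature %||% 0.25,
      y0, train_idx - 1L,
      config$epochs, config$learning_rate, config$weight_decay,
      config$epsilon, config$beta1, config$beta2
    )
  }
  out_params <- res$params
  for (nm in names(out_params)) {
    if (!is.matrix(params[[nm]])) {
      out_params[[nm]] <- as.numeric(out_params[[nm]])
    }
  }
  list(params = out_params, trace = as.numeric(res$trace))
}

#' @exportS3Method base::print
print.gnn_fit <- function(x, ...) {
  cat(
    "<gnn_fit>", x$spec$family, "on task", x$task, "-",
    length(x$loss_trace), "epochs, final loss",
    format(x$loss_trace[length(x$loss_trace)], digits = 4), "\n"
  )
  invisible(x)
}

#' Forward pass of a fitted model on a graph
#'
#' @param object A `gnn_fit`.
#' @param graph Graph to score (its feature width must match the fit).
#' @param ... Unused.
#' @return Matrix of per-node class log-probabilities (rows log-sum-exp to
#'   zero), with node and class dimnames.
#' @export
forward <- function(object, ...) {
  UseMethod("forward")
}

#' @rdname forward
#' @export
forward.gnn_fit <- function(object, graph, ...) {
  x <- model_features(object$spec, graph)
  ops <- model_operators(object$spec, graph)
  fwd <- forward_model(object$spec, object$params, object$fixed, x, ops)
  dimnames(fwd$logp) <- list(graph$nodes, object$classes)
  fwd$logp
}

# Penultimate-layer embeddings (input to the MLP head).
model_embeddings <- function(fit, graph) {
  x <- model_features(fit$spec, graph)
  ops <- model_operators(fit$spec, graph)
  fwd <- forward_model(fit$spec, fit$params, fit$fixed, x, ops)
  h2 <- fwd$h2
  rownames(h2) <- graph$nodes
  h2
}

#' Predict classes and confidences for every node
#'
#' @param object A `gnn_fit`.
#' @param graph Graph to score.
#' @param ... Unused.
#' @return A tibble with `symbol`, `.pred_class`, and one `.pred_<class>`
#'   probability column per class.
#' @export
predict.gnn_fit <- function(object, graph, ...) {
  logp <- forward(object, graph)
  probs <- exp(logp)
  out <- tibble(
    symbol = graph$nodes,
    .pred_class = factor(object$classes[max.col(probs)], levels = object$classes)
  )
  for (cl in object$classes) {
    out[[paste0(".pred_", cl)]] <- probs[, cl]
  }
  out
}

#' @export
tidy.gnn_fit <- function(x, ...) {
  imap(x$params, function(p, nm) {
    tibble(
      parameter = nm,
      rows = NROW(p), cols = NCOL(p),
      n = length(p), mean = mean(p), sd = stats::sd(as.numeric(p)),
      l2_norm = sqrt(sum(p^2))
    )
  }) |> bind_rows()
}

#' @export
glance.gnn_fit <- function(x, ...) {
  tibble(
    family = x$spec$family,
    task = x$task,
    featureless = x$spec$featureless,
    hidden = x$spec$hidden,
    epochs = length(x$loss_trace),
    final_loss = x$loss_trace[length(x$loss_trace)],
    n_parameters = sum(map_int(x$params, length))
  )
}
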