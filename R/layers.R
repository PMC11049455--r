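# Message-passing and attention layer primitives. Each exported function is
# a pure forward operation on a node-embedding matrix; the training engine
# (model.R) re-uses the same algebra with cached intermediates for
# reverse-mode gradients.

resolve_activation <- function(activation) {
  if (is.function(activation)) {
    return(activation)
  }
  switch(match.arg(activation, c("relu", "identity")),
    relu = relu,
    identity = identity
  )
}

#' Normalize an adjacency matrix for graph convolution
#'
#' With `self_loops = TRUE` the identity is added first. `"row"` scales each
#' row by 1/deg(v) (the literal propagation-rule normalization c_v =
#' deg(v)); `"symmetric"` scales by 1/sqrt(deg(v) deg(u)). Isolated nodes
#' keep an all-zero row (zero message).
#'
#' @param adjacency Sparse symmetric binary adjacency.
#' @param normalization `"symmetric"` or `"row"`.
#' @param self_loops Add self-connections before normalizing.
#' @return A sparse normalized operator matrix.
#' @export
normalize_adjacency <- function(adjacency,
                                normalization = c("symmetric", "row"),
                                self_loops = TRUE) {
  normalization <- match.arg(normalization)
  a <- adjacency
  if (self_loops) {
    a <- a + Diagonal(nrow(a))
  }
  deg <- rowSums(a)
  if (any(deg == 0) && !self_loops) {
    inform("isolated node(s) receive a zero message (no self loop)",
      .frequency = "once", .frequency_id = "generisk_isolated"
    )
  }
  inv <- ifelse(deg > 0, 1 / deg, 0)
  if (normalization == "row") {
    Diagonal(x = inv) %*% a
  } else {
    d_half <- Diagonal(x = sqrt(inv))
    d_half %*% a %*% d_half
  }
}

# Row-normalized neighbor operator (mean aggregation, no self loops).
row_mean_operator <- function(adjacency) {
  deg <- rowSums(adjacency)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  Diagonal(x = inv) %*% adjacency
}

#' Graph convolution layer
#'
#' Computes `activation( A_norm %*% h %*% W + b )`, where `A_norm` is the
#' (optionally self-looped) degree-normalized adjacency: every node averages
#' its neighbors' transformed embeddings with normalization factor c_v.
#'
#' @param h Node embedding matrix (nodes x d).
#' @param adjacency Sparse symmetric adjacency.
#' @param W Weight matrix (d x d_out).
#' @param b Optional bias vector (length d_out).
#' @param normalization `"symmetric"` or `"row"` (c_v = deg v).
#' @param self_loops Include each node in its own neighborhood.
#' @param activation `"relu"`, `"identity"`, or a function.
#' @return Dense matrix of new node embeddings (nodes x d_out).
#' @export
gcn_layer <- function(h, adjacency, W, b = NULL,
                      normalization = c("symmetric", "row"),
                      self_loops = TRUE, activation = "relu") {
  act <- resolve_activation(activation)
  a_norm <- normalize_adjacency(adjacency, match.arg(normalization), self_loops)
  out <- as.matrix(a_norm %*% h %*% W)
  if (!is.null(b)) {
    out <- sweep(out, 2L, b, "+")
  }
  act(out)
}

#' GraphSAGE layer
#'
#' Aggregates each node's neighborhood (mean by default, or sum),
#' concatenates the aggregate with the node's own embedding, and applies a
#' linear transform and activation:
#' `activation( [h || AGG(h_u, u in N(v))] %*% W + b )`.
#' Isolated nodes aggregate a zero vector.
#'
#' @inheritParams gcn_layer
#' @param W Weight matrix (2d x d_out), acting on the concatenation.
#' @param aggregate `"mean"` or `"sum"`.
#' @return Dense matrix of new node embeddings (nodes x d_out).
#' @export
sage_layer <- function(h, adjacency, W, b = NULL,
                       aggregate = c("mean", "sum"), activation = "relu") {
  act <- resolve_activation(activation)
  aggregate <- match.arg(aggregate)
  op <- if (aggregate == "mean") row_mean_operator(adjacency) else adjacency
  agg <- op %*% h
  out <- as.matrix(cbind2(h, agg) %*% W)
  if (!is.null(b)) {
    out <- sweep(out, 2L, b, "+")
  }
  act(out)
}

#' All-pair (dense) attention layer
#'
#' Maps embeddings to query, key and value vectors and aggregates values
#' with softmax-normalized all-pair attention:
#' `z_u' = sum_v exp(q_u . k_v) / sum_w exp(q_u . k_w) * v_v`.
#' Rows of the attention matrix sum to 1.
#'
#' @param z Node embedding matrix (nodes x d).
#' @param W_Q,W_K,W_V Query/key/value projection matrices (d x d_out).
#' @return Dense matrix of new node embeddings; the attention matrix is
#'   attached as attribute `"attention"`.
#' @export
dense_attention_layer <- function(z, W_Q, W_K, W_V) {
  z <- as.matrix(z)
  q <- z %*% W_Q
  k <- z %*% W_K
  v <- z %*% W_V
  a <- softmax_rows(tcrossprod(q, k))
  out <- a %*% v
  attr(out, "attention") <- a
  out
}

# Positive random features approximating the exponential kernel:
# phi(x)_j = m^{-1/2} exp(w_j . x - |x|^2 / 2), so that
# E[phi(q) . phi(k)] = exp(q . k). `shift` rescales rows/globally for
# numerical stability; any per-row (queries) or global (keys) positive
# rescaling cancels exactly in the attention ratio.
exp_feature_map <- function(x, w_feat, shift = NULL) {
  proj <- tcrossprod(x, w_feat) - rowSums(x^2) / 2
  shift <- shift %||% apply(proj, 1L, max)
  exp(proj - shift) / sqrt(nrow(w_feat))
}

elu1_map <- function(x) {
  ifelse(x > 0, x + 1, exp(x))
}

draw_phi_features <- function(m, d, seed) {
  set.seed(seed)
  matrix(rnorm(m * d), nrow = m, ncol = d)
}

kernelized_attention_core <- function(phi_q, phi_k, v) {
  skv <- crossprod(phi_k, v) # m x d_out
  sk <- colSums(phi_k) # m
  num <- phi_q %*% skv
  den <- as.numeric(phi_q %*% sk)
  if (any(!is.finite(den)) || any(abs(den) < 1e-300)) {
    abort("kernelized attention denominator degenerate (phi outputs ~ 0)",
      class = "generisk_numeric_error"
    )
  }
  num / den
}

#' Kernelized (linear) attention layer
#'
#' Approximates all-pair softmax attention with a nonnegative feature map
#' phi, decoupling the summation from the dot product:
#' `z_u' = phi(q_u)^T sum_v phi(k_v) v_v^T / phi(q_u)^T sum_w phi(k_w)`.
#' The two global summations are computed once and shared across nodes, so
#' the cost is linear in the number of nodes.
#'
#' @inheritParams dense_attention_layer
#' @param phi `"exp_random"` (positive random features for the exponential
#'   kernel, default), `"elu1"` (elementwise elu(x)+1), or a function
#'   mapping an n x d matrix to an n x m nonnegative feature matrix.
#' @param n_features Number of random features m (for `"exp_random"`).
#' @param seed Seed for the random feature draw.
#' @return Dense matrix of new node embeddings.
#' @export
kernelized_attention_layer <- function(z, W_Q, W_K, W_V,
                                       phi = c("exp_random", "elu1"),
                                       n_features = 64L, seed = 1L) {
  z <- as.matrix(z)
  q <- z %*% W_Q
  k <- z %*% W_K
  v <- z %*% W_V
  if (is.function(phi)) {
    # custom feature maps (e.g. closed-form kernel expansions) may take
    # signed values; only the denominator positivity is enforced
    phi_q <- phi(q)
    phi_k <- phi(k)
  } else {
    phi <- match.arg(phi)
    if (phi == "exp_random") {
      w_feat <- draw_phi_features(n_features, ncol(q), seed)
      phi_q <- exp_feature_map(q, w_feat)
      phi_k <- exp_feature_map(k, w_feat,
        shift = max(tcrossprod(k, w_feat) - rowSums(k^2) / 2)
      )
    } else {
      phi_q <- elu1_map(q)
      phi_k <- elu1_map(k)
    }
    if (any(phi_q < 0) || any(phi_k < 0)) {
      abort("phi must be a nonnegative feature map",
        class = "generisk_numeric_error"
      )
    }
  }
  kernelized_attention_core(phi_q, phi_k, v)
}
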