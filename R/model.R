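# Classifier families: two graph layers (GCN / GraphSAGE / attention) with a
# ReLU between them and an MLP head emitting log-softmax class scores, or a
# three-layer MLP baseline that ignores the adjacency. The forward pass
# caches every intermediate needed for exact reverse-mode gradients.

#' Specify a node-classifier architecture
#'
#' @param family `"gcn"`, `"sage"`, `"transformer"`, or `"mlp"`.
#' @param hidden Hidden width of the two representation layers.
#' @param featureless If `TRUE`, band features are replaced by a sparse
#'   identity surrogate (one indicator per node), the ablation configuration.
#' @param self_loops GCN only: include each node in its own neighborhood
#'   (default `TRUE`; set `FALSE` for the literal propagation rule).
#' @param normalization GCN only: `"symmetric"` or `"row"` (c_v = deg v).
#' @param aggregate SAGE only: `"mean"` or `"sum"` neighbor aggregation.
#' @param attention Transformer only: `"kernelized"` (linear cost, default)
#'   or `"dense"` (exact all-pair softmax).
#' @param n_random_features Transformer only: random-feature count m for the
#'   kernelized map.
#' @param phi Transformer only: `"exp_random"` or `"elu1"` feature map.
#' @param qk_norm Transformer only: L2-normalize queries and keys and divide
#'   by `temperature` before the (kernelized) softmax, as in the kernelized
#'   graph-transformer lineage. Keeps attention logits in a trainable range
#'   whatever the input scale; set `FALSE` for the literal unnormalized
#'   attention equations.
#' @param temperature Transformer only: attention temperature used when
#'   `qk_norm` is on (logits lie in `[-1/temperature, 1/temperature]`).
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("gcn", "sage", "transformer", "mlp"),
                       hidden = 64L,
                       featureless = FALSE,
                       self_loops = TRUE,
                       normalization = c("symmetric", "row"),
                       aggregate = c("mean", "sum"),
                       attention = c("kernelized", "dense"),
                       n_random_features = 64L,
                       phi = c("exp_random", "elu1"),
                       qk_norm = TRUE,
                       temperature = 0.25) {
  structure(
    list(
      family = match.arg(family),
      hidden = as.integer(hidden),
      featureless = isTRUE(featureless),
      self_loops = isTRUE(self_loops),
      normalization = match.arg(normalization),
      aggregate = match.arg(aggregate),
      attention = match.arg(attention),
      n_random_features = as.integer(n_random_features),
      phi = match.arg(phi),
      qk_norm = isTRUE(qk_norm),
      temperature = temperature
    ),
    class = "model_spec"
  )
}

#' @exportS3Method base::print
print.model_spec <- function(x, ...) {
  cat(
    "<model_spec>", x$family, "hidden:", x$hidden,
    if (x$featureless) "(featureless)" else "", "\n"
  )
  invisible(x)
}

glorot <- function(d1, d2) {
  s <- sqrt(6 / (d1 + d2))
  matrix(runif(d1 * d2, -s, s), nrow = d1, ncol = d2)
}

init_model <- function(spec, in_dim, n_classes, seed) {
  set.seed(seed)
  h <- spec$hidden
  params <- switch(spec$family,
    gcn = list(
      W1 = glorot(in_dim, h), b1 = numeric(h),
      W2 = glorot(h, h), b2 = numeric(h),
      W3 = glorot(h, n_classes), b3 = numeric(n_classes)
    ),
    sage = list(
      W1 = glorot(2L * in_dim, h), b1 = numeric(h),
      W2 = glorot(2L * h, h), b2 = numeric(h),
      W3 = glorot(h, n_classes), b3 = numeric(n_classes)
    ),
    transformer = list(
      Wq1 = glorot(in_dim, h), Wk1 = glorot(in_dim, h), Wv1 = glorot(in_dim, h),
      Wq2 = glorot(h, h), Wk2 = glorot(h, h), Wv2 = glorot(h, h),
      W3 = glorot(h, n_classes), b3 = numeric(n_classes)
    ),
    mlp = list(
      W1 = glorot(in_dim, h), b1 = numeric(h),
      W2 = glorot(h, h), b2 = numeric(h),
      W3 = glorot(h, n_classes), b3 = numeric(n_classes)
    )
  )
  fixed <- NULL
  if (spec$family == "transformer" && spec$attention == "kernelized" &&
    spec$phi == "exp_random") {
    m <- spec$n_random_features
    fixed <- list(
      wf1 = draw_phi_features(m, h, derive_seed(seed, "phi")),
      wf2 = draw_phi_features(m, h, derive_seed(seed, "phi") + 1L)
    )
  }
  list(params = params, fixed = fixed)
}

# Precompute the graph operators a spec needs.
model_operators <- function(spec, graph) {
  switch(spec$family,
    gcn = {
      a <- normalize_adjacency(graph$adjacency, spec$normalization, spec$self_loops)
      list(adj = a, adj_t = t(a))
    },
    sage = {
      r <- if (spec$aggregate == "mean") {
        row_mean_operator(graph$adjacency)
      } else {
        graph$adjacency
      }
      list(adj = r, adj_t = t(r))
    },
    list()
  )
}

model_features <- function(spec, graph) {
  if (spec$featureless) {
    # general sparse identity: diagonal-class operands hit slow method paths
    as(as(Diagonal(n_nodes(graph)), "generalMatrix"), "CsparseMatrix")
  } else {
    graph$features
  }
}

check_width <- function(x_cols, expected, family) {
  if (x_cols != expected) {
    abort(
      paste0(
        family, " input width mismatch: features have ", x_cols,
        " columns but the model expects ", expected
      ),
      class = "generisk_config_error"
    )
  }
}

linear_rows <- function(x, w, b) {
  out <- as.matrix(x %*% w)
  sweep(out, 2L, b, "+")
}

# --- forward passes with caches -------------------------------------------

# The first-layer aggregate (adjacency x input features) is constant across
# epochs; ops$m1, when present, carries it precomputed.
forward_gcn <- function(p, x, ops) {
  m1 <- ops$m1 %||% (ops$adj %*% x)
  n1 <- linear_rows(m1, p$W1, p$b1)
  mask1 <- n1 > 0
  h1 <- n1 * mask1
  m2 <- as.matrix(ops$adj %*% h1)
  n2 <- linear_rows(m2, p$W2, p$b2)
  mask2 <- n2 > 0
  h2 <- n2 * mask2
  list(h2 = h2, cache = list(m1 = m1, mask1 = mask1, m2 = m2, mask2 = mask2))
}

backward_gcn <- function(p, cache, dh2, ops) {
  dn2 <- dh2 * cache$mask2
  dh1 <- as.matrix(ops$adj_t %*% tcrossprod(dn2, p$W2))
  dn1 <- dh1 * cache$mask1
  list(
    W1 = as.matrix(crossprod(cache$m1, dn1)), b1 = colSums(dn1),
    W2 = crossprod(cache$m2, dn2), b2 = colSums(dn2)
  )
}

forward_sage <- function(p, x, ops) {
  m1 <- ops$m1 %||% cbind2(x, ops$adj %*% x)
  n1 <- linear_rows(m1, p$W1, p$b1)
  mask1 <- n1 > 0
  h1 <- n1 * mask1
  a2 <- as.matrix(ops$adj %*% h1)
  m2 <- cbind(h1, a2)
  n2 <- linear_rows(m2, p$W2, p$b2)
  mask2 <- n2 > 0
  h2 <- n2 * mask2
  list(h2 = h2, cache = list(m1 = m1, mask1 = mask1, h1 = h1, m2 = m2, mask2 = mask2))
}

backward_sage <- function(p, cache, dh2, ops) {
  h <- ncol(cache$h1)
  dn2 <- dh2 * cache$mask2
  dm2 <- tcrossprod(dn2, p$W2)
  dh1 <- dm2[, seq_len(h), drop = FALSE] +
    as.matrix(ops$adj_t %*% dm2[, h + seq_len(h), drop = FALSE])
  dn1 <- dh1 * cache$mask1
  list(
    W1 = as.matrix(crossprod(cache$m1, dn1)), b1 = colSums(dn1),
    W2 = crossprod(cache$m2, dn2), b2 = colSums(dn2)
  )
}

# L2-normalize rows and divide by sqrt(temperature); returns the scaled
# matrix plus the row norms needed for the backward pass.
qk_normalize <- function(x, temperature) {
  r <- sqrt(rowSums(x^2)) + 1e-12
  list(xn = x / (r * sqrt(temperature)), r = r)
}

qk_normalize_backward <- function(dxn, xn, r, temperature) {
  (dxn - temperature * xn * rowSums(xn * dxn)) / (r * sqrt(temperature))
}

attention_layer_forward <- function(h_in, wq, wk, wv, spec, wf) {
  q_raw <- as.matrix(h_in %*% wq)
  k_raw <- as.matrix(h_in %*% wk)
  v <- as.matrix(h_in %*% wv)
  if (isTRUE(spec$qk_norm)) {
    nq <- qk_normalize(q_raw, spec$temperature)
    nk <- qk_normalize(k_raw, spec$temperature)
    q <- nq$xn
    k <- nk$xn
  } else {
    q <- q_raw
    k <- k_raw
  }
  if (spec$attention == "dense") {
    a <- softmax_rows(tcrossprod(q, k))
    o <- a %*% v
    cache <- list(h_in = h_in, q = q, k = k, v = v, a = a, o = o)
  } else if (spec$phi == "exp_random") {
    phi_q <- exp_feature_map(q, wf)
    phi_k <- exp_feature_map(k, wf, shift = max(tcrossprod(k, wf) - rowSums(k^2) / 2))
    skv <- crossprod(phi_k, v)
    sk <- colSums(phi_k)
    den <- as.numeric(phi_q %*% sk)
    o <- (phi_q %*% skv) / den
    cache <- list(
      h_in = h_in, q = q, k = k, v = v, phi_q = phi_q, phi_k = phi_k,
      skv = skv, sk = sk, den = den, o = o, wf = wf
    )
  } else {
    phi_q <- elu1_map(q)
    phi_k <- elu1_map(k)
    skv <- crossprod(phi_k, v)
    sk <- colSums(phi_k)
    den <- as.numeric(phi_q %*% sk)
    o <- (phi_q %*% skv) / den
    cache <- list(
      h_in = h_in, q = q, k = k, v = v, phi_q = phi_q, phi_k = phi_k,
      skv = skv, sk = sk, den = den, o = o, wf = NULL
    )
  }
  if (spec$attention == "kernelized" &&
    (any(!is.finite(cache$den)) || any(cache$den < 1e-300))) {
    abort("kernelized attention denominator degenerate",
      class = "generisk_numeric_error"
    )
  }
  if (isTRUE(spec$qk_norm)) {
    cache$rq <- nq$r
    cache$rk <- nk$r
  }
  cache$mask <- cache$o > 0
  cache$h_out <- cache$o * cache$mask
  cache
}

attention_layer_backward <- function(cache, dh_out, wq, wk, wv, spec,
                                     need_input_grad = TRUE) {
  do <- dh_out * cache$mask
  if (spec$attention == "dense") {
    dv <- crossprod(cache$a, do)
    da <- tcrossprod(do, cache$v)
    ds <- cache$a * (da - rowSums(da * cache$a))
    dq <- ds %*% cache$k
    dk <- crossprod(ds, cache$q)
  } else {
    dnum <- do / cache$den
    dden <- -rowSums(do * cache$o) / cache$den
    dphi_q <- tcrossprod(dnum, cache$skv) + outer(dden, cache$sk)
    dskv <- crossprod(cache$phi_q, dnum)
    dsk <- as.numeric(crossprod(cache$phi_q, dden))
    dphi_k <- tcrossprod(cache$v, dskv) +
      matrix(dsk, nrow = nrow(cache$phi_k), ncol = length(dsk), byrow = TRUE)
    dv <- cache$phi_k %*% dskv
    if (spec$phi == "exp_random") {
      gq <- dphi_q * cache$phi_q
      dq <- gq %*% cache$wf - rowSums(gq) * cache$q
      gk <- dphi_k * cache$phi_k
      dk <- gk %*% cache$wf - rowSums(gk) * cache$k
    } else {
      dq <- dphi_q * ifelse(cache$q > 0, 1, exp(cache$q))
      dk <- dphi_k * ifelse(cache$k > 0, 1, exp(cache$k))
    }
  }
  if (isTRUE(spec$qk_norm)) {
    dq <- qk_normalize_backward(dq, cache$q, cache$rq, spec$temperature)
    dk <- qk_normalize_backward(dk, cache$k, cache$rk, spec$temperature)
  }
  dh_in <- if (need_input_grad) {
    tcrossprod(dq, wq) + tcrossprod(dk, wk) + tcrossprod(dv, wv)
  }
  list(
    Wq = as.matrix(crossprod(cache$h_in, dq)),
    Wk = as.matrix(crossprod(cache$h_in, dk)),
    Wv = as.matrix(crossprod(cache$h_in, dv)),
    dh_in = dh_in
  )
}

forward_transformer <- function(p, x, fixed, spec) {
  l1 <- attention_layer_forward(x, p$Wq1, p$Wk1, p$Wv1, spec, fixed$wf1)
  l2 <- attention_layer_forward(l1$h_out, p$Wq2, p$Wk2, p$Wv2, spec, fixed$wf2)
  list(h2 = l2$h_out, cache = list(l1 = l1, l2 = l2))
}

backward_transformer <- function(p, cache, dh2, spec) {
  g2 <- attention_layer_backward(cache$l2, dh2, p$Wq2, p$Wk2, p$Wv2, spec)
  dh1 <- g2$dh_in * cache$l1$mask # relu between the two layers
  g1 <- attention_layer_backward(cache$l1, dh1, p$Wq1, p$Wk1, p$Wv1, spec,
    need_input_grad = FALSE
  )
  list(
    Wq1 = g1$Wq, Wk1 = g1$Wk, Wv1 = g1$Wv,
    Wq2 = g2$Wq, Wk2 = g2$Wk, Wv2 = g2$Wv
  )
}

forward_mlp <- function(p, x) {
  n1 <- linear_rows(x, p$W1, p$b1)
  mask1 <- n1 > 0
  h1 <- n1 * mask1
  n2 <- linear_rows(h1, p$W2, p$b2)
  mask2 <- n2 > 0
  h2 <- n2 * mask2
  list(h2 = h2, cache = list(x = x, mask1 = mask1, h1 = h1, mask2 = mask2))
}

backward_mlp <- function(p, cache, dh2) {
  dn2 <- dh2 * cache$mask2
  dh1 <- tcrossprod(dn2, p$W2)
  dn1 <- dh1 * cache$mask1
  list(
    W1 = as.matrix(crossprod(cache$x, dn1)), b1 = colSums(dn1),
    W2 = crossprod(cache$h1, dn2), b2 = colSums(dn2)
  )
}

model_input_width <- function(spec, p) {
  switch(spec$family,
    gcn = nrow(p$W1),
    mlp = nrow(p$W1),
    sage = nrow(p$W1) / 2L,
    transformer = nrow(p$Wq1)
  )
}

# Full forward pass: representation layers + MLP head + log-softmax.
forward_model <- function(spec, params, fixed, x, ops) {
  check_width(ncol(x), model_input_width(spec, params), spec$family)
  body <- switch(spec$family,
    gcn = forward_gcn(params, x, ops),
    sage = forward_sage(params, x, ops),
    transformer = forward_transformer(params, x, fixed, spec),
    mlp = forward_mlp(params, x)
  )
  z <- linear_rows(body$h2, params$W3, params$b3)
  list(logp = log_softmax(z), h2 = body$h2, cache = body$cache)
}

backward_model <- function(spec, params, fwd, gz, ops) {
  grads <- list(
    W3 = crossprod(fwd$h2, gz),
    b3 = colSums(gz)
  )
  dh2 <- tcrossprod(gz, params$W3)
  body_grads <- switch(spec$family,
    gcn = backward_gcn(params, fwd$cache, dh2, ops),
    sage = backward_sage(params, fwd$cache, dh2, ops),
    transformer = backward_transformer(params, fwd$cache, dh2, spec),
    mlp = backward_mlp(params, fwd$cache, dh2)
  )
  c(body_grads, grads)
}

# Mean negative log-likelihood on the supplied node indices, with the
# gradient w.r.t. the pre-softmax scores.
loss_and_grad <- function(spec, params, fixed, x, ops, y, idx) {
  fwd <- forward_model(spec, params, fixed, x, ops)
  lp <- fwd$logp
  loss <- -mean(lp[cbind(idx, y[idx])])
  p_soft <- exp(lp)
  gz <- matrix(0, nrow(lp), ncol(lp))
  gz[idx, ] <- p_soft[idx, , drop = FALSE]
  gz[cbind(idx, y[idx])] <- gz[cbind(idx, y[idx])] - 1
  gz <- gz / length(idx)
  list(loss = loss, grads = backward_model(spec, params, fwd, gz, ops))
}
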