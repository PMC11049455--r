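# Fixtures built in code: tiny delimited files, toy graphs, and brute-force
# oracle implementations of the layer operations.

write_gene_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("gene-symbol,chromosome-band,gene-score,syndromic", rows), path)
  path
}

write_interaction_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("interactor_a\tinteractor_b\tspecies", rows), path)
  path
}

# A gene table whose class sizes match the reference cohort exactly
# (214 high, 530 moderate, 69 low, rest none out of 12,216 genes).
reference_gene_table <- function() {
  scores <- c(
    rep(1L, 214L), rep(2L, 530L), rep(3L, 69L),
    rep(NA_integer_, 12216L - 813L)
  )
  tibble::tibble(
    symbol = sprintf("G%05d", seq_along(scores)),
    band = "1q21",
    score = scores,
    syndromic = c(rep(TRUE, 169L), rep(FALSE, 12216L - 169L))
  )
}

# Small labeled graph with multiclass sizes {none: 8, low: 4, moderate: 2,
# high: 1} on 15 nodes; a spanning cycle guarantees every gene is a node.
four_class_graph <- function(seed = 42L, scores = c(rep(NA, 8L), rep(3L, 4L), rep(2L, 2L), 1L)) {
  set.seed(seed)
  n <- length(scores)
  genes <- tibble::tibble(
    symbol = sprintf("N%02d", 1:n),
    band = sample(c("1q21", "2p16", "3q29"), n, replace = TRUE),
    score = scores,
    syndromic = FALSE
  )
  edges <- t(utils::combn(n, 2L))
  edges <- rbind(edges[stats::runif(nrow(edges)) < 0.3, ], cbind(1:n, c(2:n, 1L)))
  interactions <- tibble::tibble(
    a = genes$symbol[edges[, 1L]],
    b = genes$symbol[edges[, 2L]],
    species = "human"
  )
  build_graph(generisk:::new_gene_table(genes),
    interactions,
    tasks = c("binary", "multiclass")
  )
}

random_graph_fixture <- function(n, d, seed, p_edge = 0.35) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1L, p_edge)
  adj <- adj + t(adj)
  list(
    adjacency = methods::as(Matrix::Matrix(adj, sparse = TRUE), "CsparseMatrix"),
    h = matrix(stats::rnorm(n * d), n, d)
  )
}

# --- independent oracles (explicit per-node double loops) ------------------

gcn_layer_oracle <- function(h, adj, W, normalization = "symmetric",
                             self_loops = TRUE) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  if (self_loops) diag(adj) <- diag(adj) + 1
  deg <- rowSums(adj)
  out <- matrix(0, n, ncol(W))
  for (v in seq_len(n)) {
    acc <- numeric(ncol(W))
    for (u in seq_len(n)) {
      if (adj[v, u] == 0) next
      cvu <- if (normalization == "row") deg[v] else sqrt(deg[v] * deg[u])
      acc <- acc + (1 / cvu) * as.numeric(t(W) %*% h[u, ])
    }
    out[v, ] <- acc
  }
  pmax(out, 0)
}

sage_layer_oracle <- function(h, adj, W, aggregate = "mean") {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  out <- matrix(0, n, ncol(W))
  for (v in seq_len(n)) {
    nbrs <- which(adj[v, ] != 0)
    agg <- if (length(nbrs) == 0L) {
      numeric(ncol(h))
    } else if (aggregate == "mean") {
      colMeans(h[nbrs, , drop = FALSE])
    } else {
      colSums(h[nbrs, , drop = FALSE])
    }
    out[v, ] <- as.numeric(t(W) %*% c(h[v, ], agg))
  }
  pmax(out, 0)
}

dense_attention_oracle <- function(z, wq, wk, wv) {
  q <- z %*% wq
  k <- z %*% wk
  v <- z %*% wv
  n <- nrow(z)
  out <- matrix(0, n, ncol(wv))
  for (u in seq_len(n)) {
    logits <- vapply(seq_len(n), function(j) sum(q[u, ] * k[j, ]), numeric(1))
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in seq_len(n)) out[u, ] <- out[u, ] + w[j] * v[j, ]
  }
  out
}
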