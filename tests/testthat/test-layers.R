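# Layer primitives against explicit double-loop oracles and closed forms.

test_that("a single self-looped node with identity weights passes through", {
  adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(1, 1))
  h <- matrix(c(2, -3), 1, 2)
  out <- gcn_layer(h, adj, diag(2),
    self_loops = TRUE, normalization = "row",
    activation = "identity"
  )
  expect_equal(as.numeric(out), c(2, -3))
})

test_that("the literal propagation rule averages neighbors on a path graph", {
  adj <- Matrix::sparseMatrix(
    i = c(1, 2, 2, 3), j = c(2, 1, 3, 2),
    x = 1, dims = c(3, 3)
  )
  h <- matrix(1, 3, 1)
  out <- gcn_layer(h, adj, matrix(1),
    self_loops = FALSE, normalization = "row",
    activation = "identity"
  )
  expect_equal(out[2, 1], 1) # mean of its two neighbors
})

test_that("gcn layers match the per-node loop oracle on random graphs", {
  for (case in list(c(5L, 3L), c(10L, 4L), c(20L, 6L))) {
    fx <- random_graph_fixture(case[1L], case[2L], seed = case[1L])
    W <- matrix(stats::rnorm(case[2L] * 4L), case[2L], 4L)
    for (norm in c("symmetric", "row")) {
      for (sl in c(TRUE, FALSE)) {
        got <- suppressMessages(
          gcn_layer(fx$h, fx$adjacency, W, normalization = norm, self_loops = sl)
        )
        want <- gcn_layer_oracle(fx$h, fx$adjacency, W, norm, sl)
        expect_lt(max(abs(got - want)), 1e-6)
      }
    }
  }
})

test_that("sage aggregates a single neighbor as itself and a star as the leaf mean", {
  # node 1 -- node 2 only
  adj <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(2, 2))
  h <- matrix(c(1, 5, 2, 6), 2, 2)
  W <- rbind(matrix(0, 2, 2), diag(2)) # pick out the aggregate half
  out <- sage_layer(h, adj, W, activation = "identity")
  expect_equal(out[1, ], h[2, ])

  # star: center 1, leaves e1..e4
  adj5 <- Matrix::sparseMatrix(
    i = c(1, 1, 1, 1, 2, 3, 4, 5),
    j = c(2, 3, 4, 5, 1, 1, 1, 1), x = 1, dims = c(5, 5)
  )
  leaves <- diag(4)
  h5 <- rbind(rep(0, 4), leaves)
  W5 <- rbind(matrix(0, 4, 4), diag(4))
  out5 <- sage_layer(h5, adj5, W5, activation = "identity")
  expect_equal(out5[1, ], colMeans(leaves))
})

test_that("sage layers match the per-node loop oracle on random graphs", {
  fx <- random_graph_fixture(12L, 5L, seed = 99L)
  W <- matrix(stats::rnorm(10L * 3L), 10L, 3L)
  for (agg in c("mean", "sum")) {
    got <- sage_layer(fx$h, fx$adjacency, W, aggregate = agg)
    want <- sage_layer_oracle(fx$h, fx$adjacency, W, agg)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("dense attention is a softmax-weighted value average", {
  # N = 1: the single node receives its own value vector
  z1 <- matrix(c(1, 2), 1, 2)
  wv <- matrix(stats::rnorm(4), 2, 2)
  out1 <- dense_attention_layer(z1, diag(2), diag(2), wv)
  expect_equal(as.numeric(out1), as.numeric(z1 %*% wv))

  # identical keys: uniform attention, output = mean of values
  z <- matrix(stats::rnorm(8), 4, 2)
  wk0 <- matrix(0, 2, 2)
  out <- dense_attention_layer(z, diag(2), wk0, diag(2))
  for (u in 1:4) expect_equal(out[u, ], colMeans(z), ignore_attr = TRUE)

  # attention rows sum to one
  z6 <- matrix(stats::rnorm(18), 6, 3)
  ws <- replicate(3, matrix(stats::rnorm(9), 3, 3), simplify = FALSE)
  res <- dense_attention_layer(z6, ws[[1]], ws[[2]], ws[[3]])
  expect_equal(unname(rowSums(attr(res, "attention"))), rep(1, 6), tolerance = 1e-8)
  # and the whole layer matches the double-loop oracle
  want <- dense_attention_oracle(z6, ws[[1]], ws[[2]], ws[[3]])
  expect_lt(max(abs(res - want)), 1e-8)
})

test_that("kernelized attention is exact for N = 1 regardless of phi", {
  z1 <- matrix(c(0.3, -0.7), 1, 2)
  wv <- matrix(stats::rnorm(4), 2, 2)
  for (phi in c("exp_random", "elu1")) {
    out <- kernelized_attention_layer(z1, diag(2), diag(2), wv,
      phi = phi,
      n_features = 8L, seed = 1L
    )
    expect_equal(as.numeric(out), as.numeric(z1 %*% wv), tolerance = 1e-10)
  }
})

test_that("a truncated exponential-kernel feature map reproduces dense attention in 1-D", {
  # exp(q k) = sum_j (q^j / sqrt(j!)) (k^j / sqrt(j!)): exact feature map
  phi_taylor <- function(x, terms = 25L) {
    sapply(0:(terms - 1L), function(j) x[, 1L]^j / sqrt(factorial(j)))
  }
  set.seed(8)
  z <- matrix(stats::runif(6, -1, 1), 6, 1)
  wq <- matrix(0.9, 1, 1)
  wk <- matrix(-0.8, 1, 1)
  wv <- matrix(1.3, 1, 1)
  dense <- dense_attention_layer(z, wq, wk, wv)
  kern <- kernelized_attention_layer(z, wq, wk, wv, phi = phi_taylor)
  expect_lt(max(abs(dense - kern)), 1e-6)
})

test_that("random-feature attention converges monotonically to dense attention", {
  set.seed(21)
  n <- 8L
  d <- 3L
  z <- matrix(stats::rnorm(n * d, sd = 0.5), n, d)
  wq <- matrix(stats::rnorm(d * d, sd = 0.5), d, d)
  wk <- matrix(stats::rnorm(d * d, sd = 0.5), d, d)
  wv <- matrix(stats::rnorm(d * d), d, d)
  dense <- dense_attention_layer(z, wq, wk, wv)
  mad_at <- function(m) {
    errs <- vapply(1:10, function(s) {
      kern <- kernelized_attention_layer(z, wq, wk, wv,
        phi = "exp_random",
        n_features = m, seed = s
      )
      mean(abs(kern - dense))
    }, numeric(1))
    mean(errs)
  }
  mads <- vapply(c(64L, 512L, 4096L), mad_at, numeric(1))
  expect_true(all(diff(mads) < 0))
  expect_lt(mads[3L], 0.05)
})

test_that("degenerate feature maps trigger the numerical guard", {
  z <- matrix(stats::rnorm(6), 3, 2)
  zero_phi <- function(x) matrix(0, nrow(x), 4L)
  expect_error(
    kernelized_attention_layer(z, diag(2), diag(2), diag(2), phi = zero_phi),
    class = "generisk_numeric_error"
  )
})

test_that("isolated nodes without self-loops yield zero messages, not errors", {
  adj <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(3, 3))
  adj <- adj + Matrix::t(adj)
  h <- matrix(1, 3, 2)
  out <- suppressMessages(
    gcn_layer(h, adj, diag(2), self_loops = FALSE, normalization = "row", activation = "identity")
  )
  expect_equal(out[3, ], c(0, 0))
  out_sage <- sage_layer(h, adj, rbind(matrix(0, 2, 2), diag(2)), activation = "identity")
  expect_equal(out_sage[3, ], c(0, 0))
})
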