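two_class_graph <- function() {
  genes <- generisk:::new_gene_table(tibble::tibble(
    symbol = sprintf("N%d", 1:6),
    band = "1q21",
    score = c(NA, NA, NA, NA, 1L, 1L), # {none: 4, risk: 2}
    syndromic = FALSE
  ))
  inter <- tibble::tibble(
    a = c("N1", "N2", "N3", "N5", "N6", "N4"),
    b = c("N2", "N3", "N4", "N6", "N1", "N5"),
    species = "human"
  )
  build_graph(genes, inter, tasks = c("binary", "multiclass"))
}

test_that("upsampling equalizes a {4, 2} split by duplicating the minority", {
  g <- two_class_graph()
  b <- upsample(g, "binary", seed = 1L)
  expect_equal(length(b$nodes), 8L)
  expect_equal(unname(table(b$labels$binary)), c(4L, 4L), ignore_attr = TRUE)
  expect_equal(length(b$origin), 2L)
  # every duplicate originates from a node of its own class
  for (d in names(b$origin)) {
    expect_equal(
      as.character(b$labels$binary[[d]]),
      as.character(g$labels$binary[[b$origin[[d]]]])
    )
  }
})

test_that("an already balanced graph is returned unchanged with empty origin", {
  g <- two_class_graph()
  b1 <- upsample(g, "binary", seed = 1L)
  b2 <- upsample(b1, "binary", seed = 2L)
  expect_equal(length(b2$origin), 0L)
  expect_equal(b2$nodes, b1$nodes)
  expect_equal(as.matrix(b2$adjacency), as.matrix(b1$adjacency), ignore_attr = TRUE)
})

test_that("a 4-class {8,4,2,1} fixture gains 17 nodes with structure preserved", {
  g <- four_class_graph()
  b <- upsample(g, "multiclass", seed = 3L)
  # deficits to the majority count of 8 are 0 + 4 + 6 + 7 = 17 duplicates
  expect_equal(length(b$origin), 17L)
  expect_equal(dim(b$adjacency), c(32L, 32L))
  expect_equal(unname(table(b$labels$multiclass)), rep(8L, 4L), ignore_attr = TRUE)
  expect_true(Matrix::isSymmetric(b$adjacency))
  expect_true(all(Matrix::diag(b$adjacency) == 0))

  # each duplicate inherits exactly its source's original neighborhood
  deg <- Matrix::rowSums(b$adjacency)
  deg_orig <- Matrix::rowSums(g$adjacency)
  for (d in names(b$origin)) {
    expect_equal(deg[[d]], deg_orig[[b$origin[[d]]]])
  }
  # edges among original nodes untouched
  n0 <- length(g$nodes)
  expect_equal(
    as.matrix(b$adjacency[1:n0, 1:n0]),
    as.matrix(g$adjacency),
    ignore_attr = TRUE
  )
  # duplicate feature rows copy their source
  src_rows <- as.matrix(g$features[b$origin, , drop = FALSE])
  dup_rows <- as.matrix(b$features[n0 + seq_along(b$origin), , drop = FALSE])
  expect_equal(dup_rows, src_rows, ignore_attr = TRUE)
})

test_that("upsampling is deterministic per seed and varies across seeds", {
  g <- four_class_graph()
  b1 <- upsample(g, "multiclass", seed = 5L)
  b2 <- upsample(g, "multiclass", seed = 5L)
  b3 <- upsample(g, "multiclass", seed = 6L)
  expect_identical(b1$origin, b2$origin)
  expect_false(identical(b1$origin, b3$origin))
})

test_that("interpolated duplicates are convex same-class blends", {
  g <- four_class_graph()
  b <- upsample(g, "multiclass", mode = "interpolate", seed = 4L)
  expect_equal(unname(table(b$labels$multiclass)), rep(8L, 4L), ignore_attr = TRUE)
  feats <- as.matrix(b$features)
  expect_true(all(feats >= 0 & feats <= 1))
  # adjacency handling identical to duplicate mode
  deg <- Matrix::rowSums(b$adjacency)
  deg_orig <- Matrix::rowSums(g$adjacency)
  for (d in names(b$origin)) {
    expect_equal(deg[[d]], deg_orig[[b$origin[[d]]]])
  }
})

test_that("a class with zero members cannot be upsampled", {
  g <- four_class_graph()
  g$labels$multiclass[g$labels$multiclass == "high"] <- "moderate"
  expect_error(upsample(g, "multiclass", seed = 1L),
    "empty class",
    class = "generisk_config_error"
  )
})

test_that("the after-upsample split is stratified, disjoint, and exhaustive", {
  g <- four_class_graph()
  sp <- split_nodes(g, "multiclass", test_fraction = 0.25, seed = 9L)
  expect_equal(length(sp$graph$nodes), 32L)
  expect_equal(length(sp$test), 8L)
  expect_equal(length(sp$train), 24L)
  expect_equal(sort(c(sp$train, sp$test)), 1:32)
  # stratified: exactly a quarter of each balanced class of 8
  per_class <- table(sp$graph$labels$multiclass[sp$test])
  expect_true(all(per_class == 2L))

  sp2 <- split_nodes(g, "multiclass", test_fraction = 0.25, seed = 9L)
  expect_identical(sp$test, sp2$test)
})

test_that("the leakage-safe protocol keeps test genes out of every origin", {
  # every class needs enough originals to populate both sides of the split
  g <- four_class_graph(scores = c(
    rep(NA, 8L), rep(3L, 8L), rep(2L, 4L), rep(1L, 4L)
  ))
  sp <- split_nodes(g, "multiclass",
    test_fraction = 0.25,
    protocol = "before_upsample", seed = 11L
  )
  origins <- unname(sp$graph$origin)
  expect_length(intersect(sp$test, origins), 0L)
  expect_length(intersect(sp$test, sp$train), 0L)
  # training side is balanced
  expect_equal(
    length(unique(table(sp$graph$labels$multiclass[sp$train]))), 1L
  )
  # test side keeps only original nodes
  expect_true(all(sp$test <= length(g$nodes)))
})

test_that("splits that would empty a class are refused", {
  g <- two_class_graph()
  expect_error(split_nodes(g, "binary", test_fraction = 0.01, seed = 1L),
    class = "generisk_config_error"
  )
  expect_error(split_nodes(g, "binary", test_fraction = 1.2, seed = 1L),
    class = "generisk_config_error"
  )
})

test_that("split manifests serialize the indices and protocol", {
  g <- four_class_graph()
  sp <- split_nodes(g, "multiclass", seed = 2L)
  path <- tempfile(fileext = ".json")
  write_split_manifest(sp, path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(m$protocol, "after_upsample")
  expect_equal(sort(c(m$train, m$test)), seq_along(sp$graph$nodes))
})
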