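test_that("gene tables parse with scores, bands, and syndromic flags", {
  path <- write_gene_csv(c("FMR1,Xq27.3,1,1", "TCF4,18q21.2,2,0", "PON1,7q21.3,3,"))
  genes <- read_gene_table(path)
  expect_s3_class(genes, "gene_table")
  expect_equal(nrow(genes), 3L)
  expect_equal(genes$score, c(1L, 2L, 3L))
  expect_equal(genes$band, c("xq27.3", "18q21.2", "7q21.3"))
  expect_equal(genes$syndromic, c(TRUE, FALSE, NA))
})

test_that("duplicate symbols collapse to the highest-confidence record", {
  path <- write_gene_csv(c("FMR1,Xq27.3,3,0", "FMR1,Xq27.3,1,0", "TCF4,18q21.2,2,0"))
  expect_warning(genes <- read_gene_table(path), "duplicated")
  expect_equal(nrow(genes), 2L)
  expect_equal(genes$score[genes$symbol == "FMR1"], 1L)
})

test_that("a present score beats an absent one when collapsing duplicates", {
  path <- write_gene_csv(c("FMR1,Xq27.3,,0", "FMR1,Xq27.3,3,0"))
  expect_warning(genes <- read_gene_table(path))
  expect_equal(genes$score, 3L)
})

test_that("missing required columns and bad scores are rejected", {
  no_band <- tempfile(fileext = ".csv")
  writeLines(c("gene-symbol,gene-score", "FMR1,1"), no_band)
  expect_error(read_gene_table(no_band), class = "generisk_config_error")

  bad_score <- write_gene_csv(c("FMR1,Xq27.3,7,0"))
  expect_error(read_gene_table(bad_score), class = "generisk_parse_error")
  bad_score2 <- write_gene_csv(c("FMR1,Xq27.3,abc,0"))
  expect_error(read_gene_table(bad_score2), "row", class = "generisk_parse_error")
})

test_that("a dialect override maps nonstandard column names", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,cytoband,rank,syn", "FMR1,Xq27.3,1,1"), path)
  genes <- read_gene_table(path, dialect = list(
    symbol = "id", band = "cytoband", score = "rank", syndromic = "syn"
  ))
  expect_equal(genes$symbol, "FMR1")
  expect_equal(genes$score, 1L)
})

test_that("human filtering keeps exactly the human-tagged records in order", {
  set.seed(11)
  species <- sample(c("human", "mouse", "yeast"), 100L, replace = TRUE)
  inter <- tibble::tibble(
    a = sprintf("A%03d", 1:100), b = sprintf("B%03d", 1:100), species = species
  )
  expected <- sum(species == "human") # brute-force count of the fixture
  out <- filter_human_interactions(inter)
  expect_equal(nrow(out), expected)
  expect_equal(out$a, inter$a[inter$species == "human"])

  all_human <- dplyr::mutate(inter, species = "Homo Sapiens")
  expect_equal(filter_human_interactions(all_human), all_human)

  expect_warning(
    res <- filter_human_interactions(inter, human_tags = "zebrafish"),
    "empty"
  )
  expect_equal(nrow(res), 0L)
  expect_error(filter_human_interactions(inter, human_tags = character(0)),
    class = "generisk_config_error"
  )
})

test_that("score-to-class mapping produces the documented label schemes", {
  genes <- generisk:::new_gene_table(tibble::tibble(
    symbol = sprintf("G%d", 1:6),
    band = "1q21",
    score = c(1L, 2L, 2L, 3L, NA, NA),
    syndromic = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  ))
  mc <- make_labels(genes, "multiclass")
  expect_equal(mc$classes, c("none", "low", "moderate", "high"))
  expect_equal(unname(mc$counts), c(2L, 1L, 2L, 1L))
  bin <- make_labels(genes, "binary")
  expect_equal(unname(bin$counts[["risk"]]), 4L)
  syn <- make_labels(genes, "syndromic")
  expect_equal(unname(syn$counts[["syndromic"]]), 2L)
  expect_error(make_labels(genes, "multilabel"), class = "generisk_config_error")
})

test_that("binary positives equal the merged multiclass risk classes", {
  genes <- generisk:::new_gene_table(reference_gene_table())
  mc <- make_labels(genes, "multiclass")
  bin <- make_labels(genes, "binary")
  expect_equal(
    unname(bin$counts[["risk"]]),
    sum(mc$counts[c("high", "moderate", "low")])
  )
  syn <- make_labels(genes, "syndromic")
  expect_equal(unname(syn$counts[["syndromic"]]), 169L)
  expect_equal(unname(syn$counts[["non_syndromic"]]), 12047L)
})

test_that("an all-absent score column yields a single-class warning", {
  genes <- generisk:::new_gene_table(tibble::tibble(
    symbol = c("A", "B"), band = "1p1", score = NA_integer_, syndromic = FALSE
  ))
  expect_warning(bin <- make_labels(genes, "binary"), "single")
  expect_equal(unname(bin$counts), c(2L, 0L))
})

test_that("band encoding is one-hot with a reserved unknown category", {
  genes <- generisk:::new_gene_table(tibble::tibble(
    symbol = c("A", "B", "C"), band = c("1q21", "2p16", "1q21"),
    score = NA_integer_, syndromic = FALSE
  ))
  enc <- encode_bands(genes)
  expect_equal(ncol(enc$features), 3L) # two bands + unknown
  expect_equal(unname(Matrix::rowSums(enc$features)), rep(1, 3))
  expect_equal(enc$vocabulary, c("1q21", "2p16", "<unknown>"))

  empty <- generisk:::new_gene_table(tibble::tibble(
    symbol = "D", band = "", score = NA_integer_, syndromic = FALSE
  ))
  enc2 <- encode_bands(empty)
  expect_equal(as.numeric(enc2$features[1, "<unknown>"]), 1)
})

test_that("multi-band genes are multi-hot", {
  genes <- generisk:::new_gene_table(tibble::tibble(
    symbol = c("A", "B"), band = c("1q21,2p16", "3q29"),
    score = NA_integer_, syndromic = FALSE
  ))
  enc <- encode_bands(genes)
  expect_equal(unname(Matrix::rowSums(enc$features)), c(2, 1))
})
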