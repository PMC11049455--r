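# Metric arithmetic, ROC construction, and ranked gene lists.

test_that("specificity, sensitivity, and accuracy follow their definitions", {
  cm <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
    dimnames = list(c("none", "risk"), c("none", "risk"))
  )
  m <- metrics_from_confusion(cm)
  pos <- m$per_class[m$per_class$class == "risk", ]
  neg <- m$per_class[m$per_class$class == "none", ]
  expect_equal(pos$specificity, 0.80)
  expect_equal(pos$sensitivity, 0.90)
  expect_equal(m$accuracy, 85.0)
  # symmetric one-vs-rest: the other class swaps the two rates
  expect_equal(neg$sensitivity, 0.80)
  expect_equal(neg$specificity, 0.90)
})

test_that("perfect and degenerate predictors give the boundary rates", {
  perfect <- diag(c(5, 7))
  dimnames(perfect) <- list(c("a", "b"), c("a", "b"))
  mp <- metrics_from_confusion(perfect)
  expect_equal(mp$accuracy, 100)
  expect_true(all(mp$per_class$sensitivity == 1))
  expect_true(all(mp$per_class$f1 == 1))

  all_one <- matrix(c(10, 0, 10, 0), 2, 2, byrow = TRUE,
    dimnames = list(c("a", "b"), c("a", "b"))
  )
  md <- metrics_from_confusion(all_one)
  expect_equal(md$accuracy, 50)
  expect_equal(md$per_class$sensitivity, c(1, 0))
})

test_that("accuracy recomputed from the stored confusion matrix matches", {
  set.seed(19)
  for (k in c(2L, 4L)) {
    truth <- factor(sample(letters[1:k], 200L, replace = TRUE), levels = letters[1:k])
    pred <- factor(sample(letters[1:k], 200L, replace = TRUE), levels = letters[1:k])
    cm <- table(truth, pred)
    m <- metrics_from_confusion(unclass(cm))
    expect_equal(m$accuracy, 100 * mean(truth == pred))
    expect_equal(sum(m$confusion), 200)
  }
})

test_that("binary macro rates swap under label inversion", {
  set.seed(23)
  truth <- sample(c(0, 1), 100L, replace = TRUE)
  pred <- sample(c(0, 1), 100L, replace = TRUE)
  cm <- table(factor(truth, 0:1), factor(pred, 0:1))
  m1 <- metrics_from_confusion(unclass(cm))
  cm_inv <- table(factor(1 - truth, 0:1), factor(1 - pred, 0:1))
  m2 <- metrics_from_confusion(unclass(cm_inv))
  expect_equal(m1$per_class$sensitivity, rev(m2$per_class$sensitivity))
  expect_equal(m1$per_class$specificity, rev(m2$per_class$specificity))
})

test_that("curve-based AUC equals the concordance formulation", {
  set.seed(29)
  cases <- list(
    list(scores = stats::rnorm(80), truth = stats::runif(80) < 0.4),
    # heavy ties
    list(scores = sample(seq(0, 1, 0.1), 120, replace = TRUE), truth = stats::runif(120) < 0.5),
    list(scores = c(stats::rnorm(40, 1), stats::rnorm(40)), truth = rep(c(TRUE, FALSE), each = 40))
  )
  for (cs in cases) {
    roc <- roc_curve_points(cs$scores, cs$truth)
    auc_curve <- generisk:::auc_trapezoid(roc$fpr, roc$tpr)
    auc_rank <- generisk:::auc_concordance(cs$scores, cs$truth)
    expect_lt(abs(auc_curve - auc_rank), 1e-9)
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0))
  }
})

test_that("curve-based AUC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- stats::rnorm(150)
  truth <- stats::runif(150) < 0.45
  roc <- roc_curve_points(scores, truth)
  ours <- generisk:::auc_trapezoid(roc$fpr, roc$tpr)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("the Youden threshold separates a separable toy exactly", {
  res <- roc_optimal_threshold(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$j, 1)
  expect_equal(res$auc, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$threshold, 0.8) # lowest positive score achieves J = 1
})

test_that("random scores give a null AUC and reversal flips it", {
  set.seed(37)
  scores <- stats::runif(200)
  truth <- rep(c(TRUE, FALSE), each = 100)
  res <- roc_optimal_threshold(scores, truth)
  se <- sqrt((200 + 1) / (12 * 100 * 100))
  expect_lt(abs(res$auc - 0.5), 3 * se)
  rev_res <- roc_optimal_threshold(-scores, truth)
  expect_equal(rev_res$auc, 1 - res$auc, tolerance = 1e-12)
  expect_error(roc_optimal_threshold(scores, rep(TRUE, 200)),
    class = "generisk_config_error"
  )
})

test_that("evaluate() assembles the full report on a trained toy model", {
  g <- four_class_graph()
  sp <- split_nodes(g, "multiclass", seed = 3L)
  fit <- train(model_spec("sage", hidden = 8L), sp$graph, "multiclass", sp$train,
    train_config(epochs = 60L, seed = 1L)
  )
  m <- evaluate(fit, sp$graph, sp$test)
  expect_s3_class(m, "gnn_metrics")
  expect_equal(sum(m$confusion), length(sp$test))
  expect_true(all(m$per_class$sensitivity >= 0 & m$per_class$sensitivity <= 1, na.rm = TRUE))
  expect_equal(m$accuracy, 100 * sum(diag(m$confusion)) / sum(m$confusion))
  expect_equal(m$f1, m$f1_macro) # multiclass convention
  td <- tidy(m)
  expect_true("auc" %in% names(td))
  gl <- glance(m)
  expect_equal(gl$n_test, length(sp$test))

  orig <- evaluate(fit, sp$graph, sp$test, originals_only = TRUE)
  expect_lte(orig$n_test, m$n_test)
})

test_that("classes absent from the test set report NA rates, not zero", {
  cm <- matrix(c(5, 1, 0, 0), 2, 2, byrow = TRUE,
    dimnames = list(c("a", "b"), c("a", "b"))
  )
  m <- metrics_from_confusion(cm)
  expect_true(is.na(m$per_class$sensitivity[m$per_class$class == "b"]))
})

test_that("top-confidence lists rank predicted originals only", {
  g <- four_class_graph()
  sp <- split_nodes(g, "multiclass", seed = 3L)
  fit <- train(model_spec("sage", hidden = 8L), sp$graph, "multiclass", sp$train,
    train_config(epochs = 60L, seed = 1L)
  )
  top <- suppressWarnings(top_confidence_genes(fit, sp$graph, "none", k = 3L))
  expect_lte(nrow(top), 3L)
  expect_true(all(diff(top$confidence) <= 0))
  expect_true(all(top$confidence >= 0 & top$confidence <= 1))
  expect_false(any(grepl("\\+dup", top$symbol)))
  # every listed gene is predicted as the requested class
  pred <- predict(fit, sp$graph)
  expect_true(all(pred$.pred_class[match(top$symbol, pred$symbol)] == "none"))

  expect_warning(top_confidence_genes(fit, sp$graph, "high", k = 50L), "shorter")
  expect_error(top_confidence_genes(fit, sp$graph, "mystery"),
    class = "generisk_config_error"
  )
})

test_that("planted high-risk genes dominate the top of the ranked list", {
  accs <- vapply(1:3, function(sd) {
    co <- generate_cohort(cohort_config(n_genes = 600L, seed = 100L + sd), dir = tempfile())
    genes <- read_gene_table(co$gene_table_path)
    inter <- read_interaction_table(co$interaction_table_path)
    g <- build_graph(genes, filter_human_interactions(inter), tasks = "binary")
    sp <- split_nodes(g, "binary", seed = sd)
    fit <- train(model_spec("sage", hidden = 32L), sp$graph, "binary", sp$train,
      train_config(epochs = 150L, seed = sd)
    )
    top <- top_confidence_genes(fit, sp$graph, "risk", k = 10L)
    truth <- setNames(co$truth$class != "none", co$truth$symbol)
    mean(truth[top$symbol])
    }, numeric(1))
  expect_gte(mean(accs), 0.8)
})
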