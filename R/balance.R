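# Class balancing by graph-aware node duplication: every minority class is
# upsampled to the majority count by sampling source nodes with replacement;
# each duplicate copies (or interpolates) its source's feature row and
# replicates the source's adjacency row/column.

#' Balance a task's classes by node duplication
#'
#' Upsamples every minority class to the majority count. Each added node
#' samples a source node of that class (with replacement); its feature row
#' is a copy of the source (`mode = "duplicate"`) or a convex combination
#' with a random same-class neighbor (`mode = "interpolate"`, GraphSMOTE
#' style), and its adjacency row/column replicates the source's connections
#' to original nodes. Duplicates are not linked to their source or to each
#' other; edges among original nodes are untouched.
#'
#' @param graph A `gene_graph`.
#' @param task Task whose classes are balanced.
#' @param mode `"duplicate"` (default) or `"interpolate"`.
#' @param seed RNG seed; the operation is deterministic per seed.
#' @param sources Optional integer vector restricting which nodes may be
#'   sampled as duplication sources (used by the leakage-safe protocol).
#' @return A `balanced_graph` (also a `gene_graph`) with extra fields
#'   `origin` (named integer: new node index -> source index),
#'   `counts_before`, `counts_after`, `balanced_task`.
#' @export
upsample <- function(graph, task, mode = c("duplicate", "interpolate"),
                     seed = 1L, sources = NULL) {
  mode <- match.arg(mode)
  labels <- graph$labels[[task]]
  if (is.null(labels)) {
    abort(paste0("graph has no labels for task '", task, "'"),
      class = "generisk_config_error"
    )
  }
  n <- n_nodes(graph)
  sources <- sources %||% seq_len(n)
  counts_before <- table(labels)
  if (any(counts_before == 0L)) {
    abort(
      paste0(
        "cannot upsample empty class(es): ",
        paste(names(counts_before)[counts_before == 0L], collapse = ", ")
      ),
      class = "generisk_config_error"
    )
  }
  present <- names(counts_before)
  if (length(present) < 2L) {
    abort("at least 2 classes must be present to balance",
      class = "generisk_config_error"
    )
  }
  pool_counts <- table(labels[sources])
  if (any(pool_counts[present] == 0L)) {
    abort("cannot upsample a class with zero source members",
      class = "generisk_config_error"
    )
  }
  target <- max(pool_counts)

  set.seed(seed)
  src <- integer(0)
  for (cl in present) {
    pool <- sources[which(labels[sources] == cl)]
    deficit <- target - length(pool)
    if (deficit > 0L) {
      src <- c(src, pool[sample.int(length(pool), deficit, replace = TRUE)])
    }
  }
  k <- length(src)
  if (k == 0L) {
    out <- graph
    out$origin <- setNames(integer(0), character(0))
    out$counts_before <- counts_before
    out$counts_after <- counts_before
    out$balanced_task <- task
    class(out) <- c("balanced_graph", class(graph))
    return(out)
  }

  dup_names <- paste0(graph$nodes[src], "+dup", seq_len(k))
  nodes <- c(graph$nodes, dup_names)

  a_src <- graph$adjacency[, src, drop = FALSE] # n x k, source neighborhoods
  adjacency <- rbind(
    cbind(graph$adjacency, a_src),
    cbind(t(a_src), sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(k, k)))
  )
  dimnames(adjacency) <- list(nodes, nodes)

  feat_new <- graph$features[src, , drop = FALSE]
  if (mode == "interpolate") {
    alphas <- runif(k)
    for (d in seq_len(k)) {
      nbrs <- which(graph$adjacency[, src[d]] != 0)
      same <- nbrs[labels[nbrs] == labels[src[d]]]
      if (length(same) > 0L) {
        mate <- if (length(same) == 1L) same else sample(same, 1L)
        feat_new[d, ] <- alphas[d] * graph$features[src[d], ] +
          (1 - alphas[d]) * graph$features[mate, ]
      }
    }
  }
  features <- rbind(graph$features, feat_new)
  rownames(features) <- nodes

  labels_all <- lapply(graph$labels, function(lb) {
    out <- factor(c(as.character(lb), as.character(lb[src])), levels = levels(lb))
    names(out) <- nodes
    out
  })

  dup_rows <- graph$node_table[src, ] |>
    mutate(
      symbol = dup_names,
      is_duplicate = TRUE,
      origin = graph$nodes[src]
    )
  node_table <- bind_rows(graph$node_table, dup_rows)

  out <- new_gene_graph(
    nodes = nodes, adjacency = adjacency, features = features,
    labels = labels_all, node_table = node_table,
    band_vocabulary = graph$band_vocabulary
  )
  out$origin <- setNames(src, dup_names)
  out$counts_before <- counts_before
  out$counts_after <- table(labels_all[[task]])
  out$balanced_task <- task
  class(out) <- c("balanced_graph", class(out))
  out
}

is_original_node <- function(graph) {
  if (!is.null(graph$node_table$is_duplicate)) {
    !graph$node_table$is_duplicate
  } else {
    rep(TRUE, n_nodes(graph))
  }
}

# Stratified largest-remainder allocation of test slots across classes.
stratified_test_take <- function(class_sizes, test_fraction) {
  total <- round(test_fraction * sum(class_sizes))
  raw <- test_fraction * class_sizes
  take <- floor(raw)
  rem <- total - sum(take)
  if (rem > 0L) {
    order_rem <- order(raw - take, decreasing = TRUE)
    take[order_rem[seq_len(rem)]] <- take[order_rem[seq_len(rem)]] + 1L
  }
  take
}

#' Split nodes into train and test sets
#'
#' Stratified-by-class random split. With `protocol = "after_upsample"`
#' (paper-faithful) the balanced node set is split, so duplicates of one
#' gene may straddle train and test; a plain graph passed here is balanced
#' first. With `protocol = "before_upsample"` (leakage-safe) the original
#' nodes are split and only the training side is upsampled, so no test gene
#' informs any training duplicate.
#'
#' @param graph A `gene_graph` or `balanced_graph`.
#' @param task Task whose labels stratify the split (and drive balancing).
#' @param test_fraction Proportion of nodes assigned to the test set.
#' @param protocol `"after_upsample"` or `"before_upsample"`.
#' @param mode Upsampling mode, passed to [upsample()] when balancing is
#'   performed internally.
#' @param seed RNG seed (balancing performed internally uses a derived seed).
#' @return A `node_split` list: `graph` (the balanced graph), integer
#'   `train` and `test` index vectors (disjoint, exhaustive over the split
#'   universe), plus the protocol, seed and fraction.
#' @export
split_nodes <- function(graph, task, test_fraction = 0.25,
                        protocol = c("after_upsample", "before_upsample"),
                        mode = "duplicate", seed = 1L) {
  protocol <- match.arg(protocol)
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)", class = "generisk_config_error")
  }

  if (protocol == "after_upsample") {
    if (!inherits(graph, "balanced_graph")) {
      graph <- upsample(graph, task, mode = mode, seed = derive_seed(seed, "balance"))
    }
    labels <- graph$labels[[task]]
    set.seed(seed)
    test <- integer(0)
    present <- levels(labels)[table(labels) > 0L]
    take <- stratified_test_take(table(labels)[present], test_fraction)
    for (ci in seq_along(present)) {
      members <- which(labels == present[ci])
      if (take[ci] == 0L || take[ci] == length(members)) {
        abort(paste0(
          "test_fraction ", test_fraction, " leaves class '", present[ci],
          "' empty on one side of the split"
        ), class = "generisk_config_error")
      }
      test <- c(test, sample(members, take[ci]))
    }
    test <- sort(test)
    train <- setdiff(seq_along(labels), test)
  } else {
    labels <- graph$labels[[task]]
    orig <- which(is_original_node(graph))
    set.seed(seed)
    test <- integer(0)
    present <- levels(labels)[table(labels[orig]) > 0L]
    take <- stratified_test_take(table(labels[orig])[present], test_fraction)
    for (ci in seq_along(present)) {
      members <- orig[which(labels[orig] == present[ci])]
      if (take[ci] == 0L || take[ci] == length(members)) {
        abort(paste0(
          "test_fraction ", test_fraction, " leaves class '", present[ci],
          "' empty on one side of the split"
        ), class = "generisk_config_error")
      }
      test <- c(test, sample(members, take[ci]))
    }
    test <- sort(test)
    train_orig <- setdiff(orig, test)
    graph <- upsample(graph, task,
      mode = mode,
      seed = derive_seed(seed, "balance"), sources = train_orig
    )
    n_new <- n_nodes(graph)
    train <- c(train_orig, setdiff(seq_len(n_new), seq_along(labels)))
  }

  structure(
    list(
      graph = graph, train = as.integer(train), test = as.integer(test),
      task = task, protocol = protocol, seed = as.integer(seed),
      test_fraction = test_fraction
    ),
    class = "node_split"
  )
}

#' @exportS3Method base::print
print.node_split <- function(x, ...) {
  cat(
    "<node_split>", x$protocol, "- train:", length(x$train),
    "test:", length(x$test), "task:", x$task, "\n"
  )
  invisible(x)
}

#' Write a split manifest as JSON
#'
#' Records the protocol, seed, fraction and the train/test indices so a
#' split can be reproduced or audited.
#'
#' @param split A `node_split`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(
    list(
      task = split$task, protocol = split$protocol, seed = split$seed,
      test_fraction = split$test_fraction,
      train = split$train, test = split$test
    ),
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}
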