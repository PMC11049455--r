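# The labeled, featurized gene interaction graph G = (V, E, C): nodes are
# gene symbols from the (human-filtered) interaction table, edges are
# deduplicated undirected interactions, features are chromosome-band
# indicators, and labels exist per classification task.

new_gene_graph <- function(nodes, adjacency, features, labels, node_table,
                           band_vocabulary) {
  structure(
    list(
      nodes = nodes,
      adjacency = adjacency,
      features = features,
      labels = labels,
      node_table = node_table,
      band_vocabulary = band_vocabulary
    ),
    class = "gene_graph"
  )
}

#' Assemble the labeled gene graph
#'
#' Builds the node-classification graph from a gene table and an
#' (already human-filtered) interaction table. The node set is every symbol
#' appearing in the interactions (optionally plus isolated gene-table genes);
#' edges are deduplicated, self-interactions dropped, and the adjacency is
#' symmetric binary with a zero diagonal. Genes absent from the gene table
#' receive the no-association / non-syndromic class and the unknown band.
#'
#' @param genes A `gene_table`.
#' @param interactions Tibble with columns `a`, `b` (symbols); assumed
#'   human-filtered already.
#' @param tasks Character vector of tasks to label
#'   (subset of `"binary"`, `"multiclass"`, `"syndromic"`).
#' @param include_isolated If `TRUE`, gene-table genes absent from the
#'   interactions are kept as isolated nodes.
#' @return A `gene_graph` object: sorted `nodes`, sparse symmetric
#'   `adjacency`, sparse binary `features` (band multi-hot), per-task factor
#'   `labels`, a `node_table` tibble, and the `band_vocabulary`.
#' @export
build_graph <- function(genes, interactions,
                        tasks = c("binary", "multiclass", "syndromic"),
                        include_isolated = FALSE) {
  if (is.null(interactions) || nrow(interactions) == 0L) {
    abort("interaction list is empty: graph tasks are undefined",
      class = "generisk_config_error"
    )
  }
  tasks <- match.arg(tasks, names(risk_class_levels), several.ok = TRUE)

  nodes <- sort_symbols(c(interactions$a, interactions$b))
  if (include_isolated) {
    nodes <- sort_symbols(c(nodes, genes$symbol))
  }
  n <- length(nodes)

  ia <- match(interactions$a, nodes)
  ib <- match(interactions$b, nodes)
  keep <- ia != ib
  lo <- pmin(ia[keep], ib[keep])
  hi <- pmax(ia[keep], ib[keep])
  pair_id <- unique((lo - 1) * n + hi)
  lo <- as.integer((pair_id - 1) %/% n) + 1L
  hi <- as.integer((pair_id - 1) %% n) + 1L
  adjacency <- sparseMatrix(
    i = c(lo, hi), j = c(hi, lo), x = 1,
    dims = c(n, n), dimnames = list(nodes, nodes)
  )

  # Full per-node record: gene-table info where known, defaults elsewhere.
  node_table <- tibble(symbol = nodes) |>
    left_join(as_tibble(genes), by = "symbol") |>
    mutate(
      band = normalize_band(.data$band),
      syndromic = !is.na(.data$syndromic) & .data$syndromic
    )

  enc <- encode_bands(node_table)
  labels <- lapply(setNames(tasks, tasks), function(tk) {
    make_labels(node_table, tk)$assignments
  })
  node_table <- node_table |>
    mutate(is_duplicate = FALSE, origin = NA_character_)
  for (tk in tasks) {
    node_table[[paste0("label_", tk)]] <- as.character(labels[[tk]])
  }

  new_gene_graph(
    nodes = nodes,
    adjacency = adjacency,
    features = enc$features,
    labels = labels,
    node_table = node_table,
    band_vocabulary = enc$vocabulary
  )
}

#' @exportS3Method base::print
print.gene_graph <- function(x, ...) {
  cat(
    "<gene_graph>", length(x$nodes), "nodes,",
    sum(x$adjacency) / 2, "undirected edges,",
    ncol(x$features), "band features\n"
  )
  for (tk in names(x$labels)) {
    cat("  ", tk, ": ", paste(
      names(table(x$labels[[tk]])), as.integer(table(x$labels[[tk]])),
      sep = "=", collapse = ", "
    ), "\n", sep = "")
  }
  invisible(x)
}

n_nodes <- function(graph) length(graph$nodes)

graph_degrees <- function(graph) {
  as.numeric(rowSums(graph$adjacency))
}

#' Write a gene graph to plain-text files
#'
#' Dumps a graph as an edge-list TSV (`edges.tsv`), a node table TSV
#' (`nodes.tsv`: symbol, band, score, syndromic, per-task label), a feature
#' matrix in MatrixMarket sparse triplet format (`features.mtx`) and its
#' column names (`feature_columns.txt`).
#'
#' @param graph A `gene_graph`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_gene_graph <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tri <- summary(as(triu(graph$adjacency, k = 1), "TsparseMatrix"))
  edges <- tibble(
    from = graph$nodes[tri$i],
    to = graph$nodes[tri$j]
  ) |> arrange(.data$from, .data$to)
  readr::write_tsv(edges, file.path(dir, "edges.tsv"), progress = FALSE)
  readr::write_tsv(graph$node_table, file.path(dir, "nodes.tsv"), progress = FALSE)
  Matrix::writeMM(graph$features, file.path(dir, "features.mtx"))
  writeLines(graph$band_vocabulary, file.path(dir, "feature_columns.txt"))
  invisible(dir)
}

#' Read a gene graph written by [write_gene_graph()]
#'
#' @param dir Directory containing `edges.tsv`, `nodes.tsv`, `features.mtx`,
#'   `feature_columns.txt`.
#' @return A `gene_graph`.
#' @export
read_gene_graph <- function(dir) {
  nodes_tbl <- readr::read_tsv(file.path(dir, "nodes.tsv"),
    col_types = readr::cols(
      score = readr::col_integer(),
      syndromic = readr::col_logical(),
      is_duplicate = readr::col_logical(),
      .default = readr::col_character()
    ), progress = FALSE
  ) |> mutate(band = normalize_band(.data$band))
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  nodes <- nodes_tbl$symbol
  n <- length(nodes)
  ia <- match(edges$from, nodes)
  ib <- match(edges$to, nodes)
  adjacency <- sparseMatrix(
    i = c(ia, ib), j = c(ib, ia), x = 1,
    dims = c(n, n), dimnames = list(nodes, nodes)
  )
  vocab <- readLines(file.path(dir, "feature_columns.txt"))
  features <- Matrix::readMM(file.path(dir, "features.mtx"))
  # binary matrices may round-trip as pattern matrices; force numeric
  features <- as(as(features, "dMatrix"), "CsparseMatrix")
  dimnames(features) <- list(nodes, vocab)
  tasks <- sub("^label_", "", grep("^label_", names(nodes_tbl), value = TRUE))
  labels <- lapply(setNames(tasks, tasks), function(tk) {
    setNames(
      factor(nodes_tbl[[paste0("label_", tk)]], levels = risk_class_levels[[tk]]),
      nodes
    )
  })
  new_gene_graph(
    nodes = nodes, adjacency = adjacency, features = features,
    labels = labels, node_table = nodes_tbl, band_vocabulary = vocab
  )
}
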