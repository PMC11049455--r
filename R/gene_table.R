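# Ingest of the two delimited inputs: a SFARI-style gene table (symbol,
# chromosome band, confidence score 1-3, syndromic flag) and a PIN-style
# interaction table (interactor A, interactor B, species annotation).

default_gene_dialect <- list(
  symbol = c("gene-symbol", "gene_symbol", "symbol", "gene"),
  band = c("chromosome-band", "chromosome_band", "band", "genetic-location", "location"),
  score = c("gene-score", "gene_score", "score", "confidence", "confidence-score"),
  syndromic = c("syndromic", "syndromic-flag", "is_syndromic")
)

default_interaction_dialect <- list(
  a = c("interactor_a", "interactor-a", "a", "protein1", "gene_a", "symbol_a"),
  b = c("interactor_b", "interactor-b", "b", "protein2", "gene_b", "symbol_b"),
  species = c("species", "organism", "taxon")
)

parse_score <- function(x) {
  x <- trimws(x)
  out <- rep(NA_integer_, length(x))
  nonempty <- !is.na(x) & x != ""
  suppressWarnings(val <- as.numeric(x[nonempty]))
  bad <- is.na(val) | !val %in% c(1, 2, 3)
  if (any(bad)) {
    rows <- which(nonempty)[bad]
    abort(
      paste0(
        "unparseable confidence score (must be 1, 2, or 3) in row(s): ",
        paste(head(rows, 20L), collapse = ", ")
      ),
      class = "generisk_parse_error"
    )
  }
  out[nonempty] <- as.integer(val)
  out
}

parse_flag <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[x %in% c("0", "false", "f", "no", "n")] <- FALSE
  out
}

normalize_band <- function(x) {
  x <- tolower(trimws(x))
  x[is.na(x)] <- ""
  x
}

#' Read a SFARI-style gene table
#'
#' Parses a delimited (CSV/TSV, autodetected) table of gene records with a
#' gene symbol, a chromosome band string, an ordinal confidence score in
#' \{1, 2, 3\} (1 = most confident association), and an optional syndromic
#' flag. Duplicate symbols are collapsed to the highest-confidence record
#' (lowest score; a present score beats an absent one) with a warning.
#'
#' @param path Path to the delimited file.
#' @param dialect Optional named list overriding the column-name candidates
#'   for `symbol`, `band`, `score`, `syndromic` (each a character vector of
#'   acceptable header spellings).
#' @return A `gene_table` tibble with columns `symbol`, `band`, `score`,
#'   `syndromic`.
#' @export
read_gene_table <- function(path, dialect = NULL) {
  dialect <- modifyList(default_gene_dialect, dialect %||% list())
  raw <- read_delimited(path)
  cols <- names(raw)
  i_sym <- resolve_column(cols, dialect$symbol, "symbol")
  i_band <- resolve_column(cols, dialect$band, "band")
  i_score <- resolve_column(cols, dialect$score, "score")
  i_syn <- resolve_column(cols, dialect$syndromic, "syndromic", required = FALSE)

  genes <- tibble(
    symbol = trimws(raw[[i_sym]]),
    band = normalize_band(raw[[i_band]]),
    score = parse_score(raw[[i_score]]),
    syndromic = if (is.na(i_syn)) NA else parse_flag(raw[[i_syn]])
  )
  if (any(is.na(genes$symbol) | genes$symbol == "")) {
    abort("gene table contains empty symbols", class = "generisk_parse_error")
  }

  if (anyDuplicated(genes$symbol)) {
    dup <- unique(genes$symbol[duplicated(genes$symbol)])
    warn(paste0(
      length(dup), " duplicated symbol(s) collapsed to the highest-confidence record: ",
      paste(head(dup, 5L), collapse = ", ")
    ))
    genes <- genes |>
      mutate(.rank = ifelse(is.na(.data$score), 4L, .data$score)) |>
      arrange(.data$symbol, .data$.rank) |>
      distinct(.data$symbol, .keep_all = TRUE) |>
      select(-".rank")
  }
  new_gene_table(genes)
}

new_gene_table <- function(x) {
  structure(as_tibble(x), class = c("gene_table", class(as_tibble(x))))
}

#' Read a PIN-style interaction table
#'
#' Parses a delimited (CSV/TSV, autodetected) table of pairwise gene/protein
#' interactions with a species annotation column.
#'
#' @inheritParams read_gene_table
#' @return A tibble with columns `a`, `b`, `species`.
#' @export
read_interaction_table <- function(path, dialect = NULL) {
  dialect <- modifyList(default_interaction_dialect, dialect %||% list())
  raw <- read_delimited(path)
  cols <- names(raw)
  i_a <- resolve_column(cols, dialect$a, "interactor a")
  i_b <- resolve_column(cols, dialect$b, "interactor b")
  i_sp <- resolve_column(cols, dialect$species, "species")
  out <- tibble(
    a = trimws(raw[[i_a]]),
    b = trimws(raw[[i_b]]),
    species = trimws(raw[[i_sp]])
  )
  if (any(out$a == "" | out$b == "" | is.na(out$a) | is.na(out$b))) {
    abort("interaction table contains empty interactor symbols",
      class = "generisk_parse_error"
    )
  }
  out
}

#' Keep only human interactions
#'
#' Drops every interaction whose species annotation does not match one of the
#' supplied human tags (case-insensitive, whitespace-trimmed). Row order is
#' preserved.
#'
#' @param interactions A tibble/data frame with columns `a`, `b`, `species`.
#' @param human_tags Nonempty character vector of annotations counted as
#'   human (e.g. `"human"`, `"Homo sapiens"`, `"9606"`).
#' @return The filtered tibble, in the original order.
#' @export
filter_human_interactions <- function(interactions,
                                      human_tags = c("human", "homo sapiens", "9606")) {
  if (length(human_tags) == 0L) {
    abort("human_tags must be nonempty", class = "generisk_config_error")
  }
  tags <- tolower(trimws(human_tags))
  keep <- tolower(trimws(interactions$species)) %in% tags
  out <- as_tibble(interactions)[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warn("no interactions matched the human tags; the filtered set is empty")
  }
  out
}

risk_class_levels <- list(
  binary = c("none", "risk"),
  multiclass = c("none", "low", "moderate", "high"),
  syndromic = c("non_syndromic", "syndromic")
)

# SFARI scores are ordered most- to least-confident, so score 1 maps to the
# high-association class, 2 to moderate, 3 to low.
score_to_multiclass <- function(score) {
  out <- rep("none", length(score))
  out[!is.na(score) & score == 1L] <- "high"
  out[!is.na(score) & score == 2L] <- "moderate"
  out[!is.na(score) & score == 3L] <- "low"
  out
}

#' Build per-gene labels for a classification task
#'
#' Maps gene records onto task labels. `binary`: any gene with a confidence
#' score is `risk`, everything else `none`. `multiclass`: score 1 ->
#' `high`, 2 -> `moderate`, 3 -> `low` association, absent -> `none`.
#' `syndromic`: from the syndromic flag (absent flag counts as
#' non-syndromic).
#'
#' @param genes A `gene_table` (or compatible tibble).
#' @param task One of `"binary"`, `"multiclass"`, `"syndromic"`.
#' @return A `label_scheme` list with elements `task`, `classes` (ordered
#'   class names, negative class first), `counts` (named integer vector),
#'   and `assignments` (factor named by gene symbol).
#' @export
make_labels <- function(genes, task) {
  if (!is.character(task) || length(task) != 1L ||
    !task %in% names(risk_class_levels)) {
    abort(
      "task must be one of 'binary', 'multiclass', 'syndromic'",
      class = "generisk_config_error"
    )
  }
  lv <- risk_class_levels[[task]]
  lab <- switch(task,
    binary = ifelse(is.na(genes$score), "none", "risk"),
    multiclass = score_to_multiclass(genes$score),
    syndromic = ifelse(!is.na(genes$syndromic) & genes$syndromic,
      "syndromic", "non_syndromic"
    )
  )
  assignments <- factor(lab, levels = lv)
  names(assignments) <- genes$symbol
  counts <- table(assignments)
  if (sum(counts > 0L) < 2L) {
    warn(paste0("task '", task, "' has a single observed class"))
  }
  structure(
    list(
      task = task,
      classes = lv,
      counts = setNames(as.integer(counts), names(counts)),
      assignments = assignments
    ),
    class = "label_scheme"
  )
}

#' @exportS3Method base::print
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> task:", x$task, "\n")
  print(x$counts)
  invisible(x)
}

#' One-hot / multi-hot encode chromosome bands
#'
#' Builds the node feature matrix: the vocabulary is the sorted set of
#' distinct observed band strings plus one reserved unknown category. Genes
#' annotated at several bands (separated by `,`, `;`, `|`, or `/`) are
#' multi-hot; genes with an empty band get the unknown indicator only.
#'
#' @param genes A `gene_table` (or compatible tibble with `symbol`, `band`).
#' @param unknown_label Name of the reserved unknown-band category.
#' @return A list with `features` (sparse binary gene x band matrix with
#'   dimnames) and `vocabulary` (character vector of feature columns).
#' @export
encode_bands <- function(genes, unknown_label = "<unknown>") {
  if (nrow(genes) == 0L) {
    abort("gene table is empty", class = "generisk_config_error")
  }
  split_bands <- strsplit(normalize_band(genes$band), "[,;|/]+")
  split_bands <- lapply(split_bands, function(b) {
    b <- trimws(b)
    b[b != ""]
  })
  observed <- sort_symbols(unlist(split_bands))
  vocab <- c(observed, unknown_label)
  idx <- lapply(split_bands, function(b) {
    if (length(b) == 0L) length(vocab) else match(unique(b), vocab)
  })
  i <- rep(seq_along(idx), lengths(idx))
  j <- unlist(idx)
  features <- sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(nrow(genes), length(vocab)),
    dimnames = list(genes$symbol, vocab)
  )
  list(features = features, vocabulary = vocab)
}
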