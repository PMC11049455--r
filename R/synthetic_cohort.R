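# Synthetic SFARI-like / PIN-like cohort generator. Produces the two
# delimited tables the ingest module consumes, with planted class sizes,
# chromosome-band signal, and degree-corrected planted-partition edges with
# tunable homophily between risk genes, plus a truth table for validation.

reference_class_counts <- c(high = 214L, moderate = 530L, low = 69L, none = 11403L)
reference_n_genes <- 12216L
reference_syndromic <- 169L

scale_class_counts <- function(n_genes) {
  counts <- round(reference_class_counts * n_genes / reference_n_genes)
  counts["none"] <- counts["none"] + (n_genes - sum(counts))
  counts
}

#' Configuration for a synthetic gene cohort
#'
#' Defaults emulate the real cohort: ~12k genes in the class ratio
#' 214:530:69:11403 (high/moderate/low/none association), a 169:12047
#' syndromic split (scaled to `n_genes`), a 471-band vocabulary, band-label
#' signal 0.8 (a risk gene draws its band from a risk-enriched subset
#' covering 10% of the vocabulary with this probability), within-risk edge
#' homophily 5, and mean degree 20 under a degree-corrected planted
#' partition with lognormal degree propensities.
#'
#' @param n_genes Number of genes.
#' @param class_counts Named integer vector (`high`, `moderate`, `low`,
#'   `none`) summing to `n_genes`; default is the reference ratio scaled.
#' @param syndromic_count Number of syndromic genes (default scaled from
#'   169/12216); drawn preferentially (80%) among risk genes.
#' @param n_bands Size of the chromosome-band vocabulary.
#' @param band_signal Probability a risk gene draws its band from the
#'   risk-enriched subset.
#' @param homophily Multiplier (>= 1) on the edge probability of pairs whose
#'   endpoints are both risk genes.
#' @param mean_degree Expected edges per node.
#' @param theta_sd Log-scale SD of the lognormal degree propensities.
#' @param risk_band_fraction Fraction of the vocabulary in the risk-enriched
#'   subset.
#' @param decoy_edge_fraction Fraction of extra non-human decoy interactions
#'   appended to exercise the species filter.
#' @param seed RNG seed for the generator.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 12216L,
                          class_counts = NULL,
                          syndromic_count = NULL,
                          n_bands = 471L,
                          band_signal = 0.8,
                          homophily = 5,
                          mean_degree = 20,
                          theta_sd = 0.75,
                          risk_band_fraction = 0.1,
                          decoy_edge_fraction = 0.05,
                          seed = 1L) {
  n_genes <- as.integer(n_genes)
  class_counts <- class_counts %||% scale_class_counts(n_genes)
  class_counts <- setNames(as.integer(class_counts), names(class_counts))
  if (!setequal(names(class_counts), names(reference_class_counts))) {
    abort("class_counts must be named high, moderate, low, none",
      class = "generisk_config_error"
    )
  }
  if (sum(class_counts) != n_genes) {
    abort("class_counts must sum to n_genes", class = "generisk_config_error")
  }
  syndromic_count <- as.integer(
    syndromic_count %||% round(reference_syndromic * n_genes / reference_n_genes)
  )
  stopifnot_scalar_prob(band_signal, "band_signal")
  stopifnot_scalar_prob(risk_band_fraction, "risk_band_fraction")
  stopifnot_scalar_prob(decoy_edge_fraction, "decoy_edge_fraction")
  if (homophily < 1) {
    abort("homophily must be >= 1", class = "generisk_config_error")
  }
  if (mean_degree <= 0 || mean_degree >= n_genes) {
    abort("mean_degree must be in (0, n_genes)", class = "generisk_config_error")
  }
  structure(
    list(
      n_genes = n_genes, class_counts = class_counts,
      syndromic_count = syndromic_count, n_bands = as.integer(n_bands),
      band_signal = band_signal, homophily = homophily,
      mean_degree = mean_degree, theta_sd = theta_sd,
      risk_band_fraction = risk_band_fraction,
      decoy_edge_fraction = decoy_edge_fraction, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

make_band_vocabulary <- function(n_bands) {
  # lowercase throughout so the written tables match the ingest path's
  # case normalization exactly
  chroms <- c(1:22, "x", "y")
  combos <- expand.grid(
    chrom = chroms, arm = c("p", "q"), major = 1:3, minor = 1:26,
    stringsAsFactors = FALSE
  )
  labs <- paste0(combos$chrom, combos$arm, combos$major, ".", combos$minor)
  unique(labs)[seq_len(n_bands)]
}

# fastRG-style sampler for one block pair: the number of edge slots is
# Poisson with the block's expected rate, endpoints are drawn proportional
# to the degree propensities theta within each block.
sample_block_edges <- function(idx_r, idx_s, theta, rate) {
  m <- rpois(1L, rate)
  if (m == 0L) {
    return(NULL)
  }
  pr <- theta[idx_r] / sum(theta[idx_r])
  ps <- theta[idx_s] / sum(theta[idx_s])
  cbind(
    idx_r[sample.int(length(idx_r), m, replace = TRUE, prob = pr)],
    idx_s[sample.int(length(idx_s), m, replace = TRUE, prob = ps)]
  )
}

#' Generate a synthetic cohort on disk
#'
#' Writes `gene_table.tsv` (every gene with symbol, band, score - empty for
#' non-risk genes - and syndromic flag), `interactions.tsv` (human edges
#' from the planted-partition model plus a fraction of non-human decoys),
#' and `truth.tsv` (symbol, class, syndromic, band) into `dir`.
#' Deterministic for a fixed config seed.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if missing).
#' @return A `gene_cohort` object with the file paths, the truth tibble and
#'   the config.
#' @export
generate_cohort <- function(config, dir = tempfile("cohort")) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  n <- config$n_genes
  symbols <- sprintf("G%05d", seq_len(n))

  cls <- sample(rep(names(config$class_counts), config$class_counts))
  is_risk <- cls != "none"

  # Syndromic flags: 80% among risk genes where possible.
  n_syn <- min(config$syndromic_count, n)
  n_syn_risk <- min(round(0.8 * n_syn), sum(is_risk))
  syn_idx <- c(
    sample(which(is_risk), n_syn_risk),
    sample(which(!is_risk), n_syn - n_syn_risk)
  )
  syndromic <- seq_len(n) %in% syn_idx

  # Bands: risk genes draw from a risk-enriched subset with prob band_signal.
  vocab <- make_band_vocabulary(config$n_bands)
  n_enriched <- max(1L, round(config$risk_band_fraction * length(vocab)))
  enriched <- vocab[seq_len(n_enriched)]
  band <- sample(vocab, n, replace = TRUE)
  from_enriched <- is_risk & runif(n) < config$band_signal
  band[from_enriched] <- sample(enriched, sum(from_enriched), replace = TRUE)

  # Degree-corrected planted partition over the four classes: pairs within
  # the same risk class (high-high, moderate-moderate, low-low) have their
  # edge rate multiplied by `homophily`; every other pair is background.
  theta <- rlnorm(n, meanlog = 0, sdlog = config$theta_sd)
  class_names <- names(config$class_counts)
  blocks <- lapply(setNames(class_names, class_names), function(cl) which(cls == cl))
  s <- map_dbl(blocks, function(ix) sum(theta[ix]))
  rates <- list()
  for (ri in seq_along(class_names)) {
    for (si in ri:length(class_names)) {
      r <- class_names[ri]
      q <- class_names[si]
      mult <- if (r == q && r != "none") config$homophily else 1
      lambda <- if (r == q) mult * s[[r]]^2 / 2 else mult * s[[r]] * s[[q]]
      rates[[paste(r, q)]] <- list(a = r, b = q, lambda = lambda)
    }
  }
  rho <- (n * config$mean_degree / 2) / sum(map_dbl(rates, "lambda"))
  pairs <- do.call(rbind, map(rates, function(rt) {
    sample_block_edges(blocks[[rt$a]], blocks[[rt$b]], theta, rho * rt$lambda)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    abort("generator produced no edges; increase mean_degree",
      class = "generisk_config_error"
    )
  }
  keep <- pairs[, 1L] != pairs[, 2L]
  lo <- pmin(pairs[keep, 1L], pairs[keep, 2L])
  hi <- pmax(pairs[keep, 1L], pairs[keep, 2L])
  pair_id <- unique((lo - 1) * n + hi)
  lo <- as.integer((pair_id - 1) %/% n) + 1L
  hi <- as.integer((pair_id - 1) %% n) + 1L

  human <- tibble(
    interactor_a = symbols[lo], interactor_b = symbols[hi], species = "human"
  )
  n_decoy <- round(config$decoy_edge_fraction * nrow(human))
  decoy <- tibble(
    interactor_a = symbols[sample.int(n, n_decoy, replace = TRUE)],
    interactor_b = symbols[sample.int(n, n_decoy, replace = TRUE)],
    species = sample(c("mouse", "yeast"), n_decoy, replace = TRUE)
  )
  interactions <- bind_rows(human, decoy)
  interactions <- interactions[sample.int(nrow(interactions)), ]

  gene_table <- tibble(
    `gene-symbol` = symbols,
    `chromosome-band` = band,
    `gene-score` = dplyr::case_match(cls,
      "high" ~ "1", "moderate" ~ "2", "low" ~ "3", "none" ~ ""
    ),
    syndromic = as.integer(syndromic)
  )
  truth <- tibble(
    symbol = symbols, class = cls, syndromic = syndromic, band = band
  )

  paths <- list(
    gene_table_path = file.path(dir, "gene_table.tsv"),
    interaction_table_path = file.path(dir, "interactions.tsv"),
    truth_path = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(gene_table, paths$gene_table_path, progress = FALSE)
  readr::write_tsv(interactions, paths$interaction_table_path, progress = FALSE)
  readr::write_tsv(truth, paths$truth_path, progress = FALSE)

  structure(
    c(paths, list(dir = dir, truth = truth, config = config)),
    class = "gene_cohort"
  )
}

#' @exportS3Method base::print
print.gene_cohort <- function(x, ...) {
  cat(
    "<gene_cohort>", x$config$n_genes, "genes in", x$dir, "\n  classes:",
    paste(names(x$config$class_counts), x$config$class_counts,
      sep = "=", collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' Summarize a generated cohort from its files
#'
#' Re-reads the written tables and reports class counts, edge and degree
#' statistics, the observed band-vocabulary size, and an empirical homophily
#' estimate (edge density among pairs of the same risk class over the
#' density of all other pairs).
#'
#' @param cohort A `gene_cohort` from [generate_cohort()].
#' @return A one-row tibble of summary statistics.
#' @export
summarize_cohort <- function(cohort) {
  genes <- read_gene_table(cohort$gene_table_path)
  inter <- read_interaction_table(cohort$interaction_table_path)
  human <- suppressWarnings(filter_human_interactions(inter))
  ml <- make_labels(genes, "multiclass")
  counts <- ml$counts
  n <- nrow(genes)
  cls_a <- as.character(ml$assignments[human$a])
  cls_b <- as.character(ml$assignments[human$b])
  same_risk <- cls_a == cls_b & cls_a != "none"
  e_same <- sum(same_risk)
  e_other <- sum(!same_risk)
  risk_counts <- counts[setdiff(names(counts), "none")]
  pairs_same <- sum(risk_counts * (risk_counts - 1) / 2)
  pairs_other <- n * (n - 1) / 2 - pairs_same
  homophily_ratio <- (e_same / pairs_same) / (e_other / pairs_other)

  deg <- table(factor(c(human$a, human$b), levels = genes$symbol))
  tibble(
    n_genes = n,
    n_edges_human = nrow(human),
    n_edges_total = nrow(inter),
    mean_degree = mean(as.integer(deg)),
    max_degree = max(as.integer(deg)),
    n_bands_observed = length(setdiff(unique(genes$band), "")),
    homophily_ratio = homophily_ratio,
    n_high = counts[["high"]],
    n_moderate = counts[["moderate"]],
    n_low = counts[["low"]],
    n_none = counts[["none"]],
    n_syndromic = sum(genes$syndromic, na.rm = TRUE)
  )
}
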