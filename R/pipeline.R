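# One-call orchestration: generate/ingest -> build -> balance -> split ->
# train -> evaluate -> report, with a JSON manifest so any run can be
# reproduced exactly from its output directory.

#' Build a pipeline run configuration
#'
#' @param task Classification task (`"binary"`, `"multiclass"`,
#'   `"syndromic"`).
#' @param models Character vector of model variants: a family name
#'   (`"gcn"`, `"sage"`, `"transformer"`, `"mlp"`) optionally suffixed with
#'   `"_featureless"` for the ablation variant of a graph family.
#' @param data Either `list(type = "synthetic", ...)` with [cohort_config()]
#'   arguments, or `list(type = "files", gene_table = path,
#'   interactions = path, human_tags = ...)`.
#' @param balance `list(mode=, protocol=, test_fraction=)` controlling
#'   [split_nodes()].
#' @param train A [train_config()] or a list of its arguments.
#' @param out_dir Output directory for all artifacts.
#' @param seed Global seed; stage seeds are derived from it.
#' @param hidden Hidden width for every model.
#' @return A `run_config`.
#' @export
run_config <- function(task = "binary",
                       models = c("gcn", "sage", "transformer", "mlp"),
                       data = list(type = "synthetic"),
                       balance = list(),
                       train = list(),
                       out_dir = tempfile("generisk_run"),
                       seed = 1L,
                       hidden = 64L) {
  balance <- modifyList(
    list(mode = "duplicate", protocol = "after_upsample", test_fraction = 0.25),
    balance
  )
  if (!inherits(train, "train_config")) {
    train <- do.call(train_config, train)
  }
  structure(
    list(
      task = task, models = models, data = data, balance = balance,
      train = train, out_dir = out_dir, seed = as.integer(seed),
      hidden = as.integer(hidden)
    ),
    class = "run_config"
  )
}

#' Load a pipeline run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

parse_model_variant <- function(name, hidden) {
  featureless <- grepl("_featureless$", name)
  family <- sub("_featureless$", "", name)
  if (featureless && family == "mlp") {
    abort("the MLP baseline has no featureless graph variant",
      class = "generisk_config_error"
    )
  }
  model_spec(family, hidden = hidden, featureless = featureless)
}

mark_stage <- function(out_dir, stage) {
  writeLines(stage, file.path(out_dir, "STAGE"))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order - data generation or ingest, human
#' filtering, graph assembly, class balancing, train/test split, training
#' of every requested model variant, evaluation - and writes all artifacts
#' (graph dump, split manifest, per-model metrics JSON and loss traces, a
#' comparison table, and a `manifest.json` from which the run can be
#' reproduced) to the output directory. A `STAGE` marker file records the
#' last stage reached, so partial outputs of a failed run are identifiable.
#'
#' @param config A [run_config()] (or YAML path).
#' @return A `pipeline_run`: manifest, comparison tibble, and named lists
#'   of `gnn_metrics` (upsampled test set) and `metrics_originals`
#'   (originals-only test nodes), plus the fitted models.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- load_run_config(config)
  }
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  mark_stage(out_dir, "data")
  data_seed <- derive_seed(config$seed, "cohort")
  if (identical(config$data$type, "synthetic")) {
    cohort_args <- config$data[setdiff(names(config$data), "type")]
    cohort_args$seed <- cohort_args$seed %||% data_seed
    cohort <- generate_cohort(
      do.call(cohort_config, cohort_args),
      dir = file.path(out_dir, "cohort")
    )
    gene_path <- cohort$gene_table_path
    inter_path <- cohort$interaction_table_path
    human_tags <- c("human", "homo sapiens", "9606")
  } else {
    gene_path <- config$data$gene_table
    inter_path <- config$data$interactions
    human_tags <- config$data$human_tags %||% c("human", "homo sapiens", "9606")
  }
  genes <- read_gene_table(gene_path)
  interactions <- read_interaction_table(inter_path)

  mark_stage(out_dir, "build")
  human <- filter_human_interactions(interactions, human_tags)
  graph <- build_graph(genes, human, tasks = config$task)

  mark_stage(out_dir, "balance_split")
  split_seed <- derive_seed(config$seed, "split")
  split <- split_nodes(
    graph, config$task,
    test_fraction = config$balance$test_fraction,
    protocol = config$balance$protocol,
    mode = config$balance$mode,
    seed = split_seed
  )
  write_gene_graph(split$graph, file.path(out_dir, "graph"))
  write_split_manifest(split, file.path(out_dir, "split.json"))

  mark_stage(out_dir, "train_evaluate")
  fits <- list()
  metrics <- list()
  metrics_originals <- list()
  for (variant in config$models) {
    spec <- parse_model_variant(variant, config$hidden)
    tcfg <- config$train
    tcfg$seed <- derive_seed(config$seed, "train") + match(variant, config$models)
    fit <- train(spec, split$graph, config$task, split$train, tcfg)
    m_up <- evaluate(fit, split$graph, split$test)
    m_orig <- evaluate(fit, split$graph, split$test, originals_only = TRUE)
    fits[[variant]] <- fit
    metrics[[variant]] <- m_up
    metrics_originals[[variant]] <- m_orig
    jsonlite::write_json(
      list(
        variant = variant,
        upsampled_test = glance(m_up),
        originals_only = glance(m_orig),
        per_class = tidy(m_up)
      ),
      file.path(out_dir, paste0("metrics_", variant, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    readr::write_csv(
      tibble(epoch = seq_along(fit$loss_trace), loss = fit$loss_trace),
      file.path(out_dir, paste0("loss_", variant, ".csv")),
      progress = FALSE
    )
  }

  mark_stage(out_dir, "report")
  comparison <- map(names(metrics), function(v) {
    glance(metrics[[v]]) |>
      mutate(
        model = v,
        accuracy_originals = metrics_originals[[v]]$accuracy, .before = 1L
      )
  }) |> bind_rows()
  readr::write_tsv(comparison, file.path(out_dir, "comparison.tsv"), progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("generisk")),
    seed = config$seed,
    derived_seeds = list(
      cohort = data_seed, split = split_seed,
      train_base = derive_seed(config$seed, "train")
    ),
    task = config$task,
    models = config$models,
    data = config$data,
    balance = config$balance,
    train = unclass(config$train),
    hidden = config$hidden,
    class_counts = as.list(table(split$graph$labels[[config$task]]))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  mark_stage(out_dir, "done")

  structure(
    list(
      manifest = manifest, comparison = comparison,
      metrics = metrics, metrics_originals = metrics_originals,
      fits = fits, split = split, out_dir = out_dir
    ),
    class = "pipeline_run"
  )
}

#' Re-run a pipeline from a written manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir New output directory.
#' @return A `pipeline_run`.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir = tempfile("generisk_rerun")) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- run_config(
    task = m$task,
    models = m$models,
    data = as.list(m$data),
    balance = as.list(m$balance),
    train = do.call(train_config, as.list(m$train)),
    out_dir = out_dir,
    seed = m$seed,
    hidden = m$hidden
  )
  run_pipeline(cfg)
}

#' @exportS3Method base::print
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> task:", x$manifest$task, "in", x$out_dir, "\n")
  print(as.data.frame(x$comparison), digits = 4)
  invisible(x)
}

#' Combine several runs into one comparison table
#'
#' Stacks the comparison rows of multiple [run_pipeline()] results. Runs
#' must share the same task, data seed and split seed - otherwise their
#' metrics are not comparable and the call refuses.
#'
#' @param runs A list of `pipeline_run` objects (a single run is allowed).
#' @return A tibble, one row per model variant per run.
#' @export
compare_models <- function(runs) {
  if (inherits(runs, "pipeline_run")) {
    runs <- list(runs)
  }
  key <- function(r) {
    paste(
      r$manifest$task, r$manifest$derived_seeds$cohort,
      r$manifest$derived_seeds$split
    )
  }
  keys <- map_chr(runs, key)
  if (length(unique(keys)) > 1L) {
    abort("runs use different data/split seeds or tasks; refusing to compare",
      class = "generisk_config_error"
    )
  }
  map(runs, function(r) r$comparison) |>
    bind_rows() |>
    distinct(.data$model, .keep_all = TRUE)
}
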