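# Shared numerical and plumbing helpers.

#' Derive a stage-specific seed from a single global seed
#'
#' A single user-facing seed fans out to per-stage seeds (cohort generation,
#' upsampling, splitting, weight initialization, random attention features,
#' projection) so that individual stages can be re-run in isolation while a
#' full run stays reproducible end to end.
#'
#' @param seed Integer global seed.
#' @param stage One of `"cohort"`, `"graph"`, `"balance"`, `"split"`,
#'   `"init"`, `"phi"`, `"projection"`, `"train"`.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(
    cohort = 101L, graph = 211L, balance = 307L, split = 401L,
    init = 503L, phi = 601L, projection = 701L, train = 809L
  )
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown seed stage: ", stage), class = "generisk_config_error")
  }
  as.integer(((as.numeric(seed) %% 1000003) * 2099 + offsets[[stage]]) %% 2147483629)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise numerically stable log-softmax; returns a dense matrix whose rows
# log-sum-exp to zero. Row maxima via columnwise pmax (few classes, many rows).
row_max <- function(z) {
  m <- z[, 1L]
  for (j in seq_len(ncol(z))[-1L]) {
    m <- pmax(m, z[, j])
  }
  m
}

log_softmax <- function(z) {
  z <- as.matrix(z)
  zs <- z - row_max(z)
  zs - log(rowSums(exp(zs)))
}

softmax_rows <- function(z) {
  exp(log_softmax(z))
}

# Delimiter sniffing for the two ingest readers: tab wins if the header line
# contains any tab, else comma.
detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    abort(paste0("empty file: ", path), class = "generisk_config_error")
  }
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_delimited <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "generisk_config_error")
  }
  delim <- delim %||% detect_delim(path)
  readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
}

# Resolve one canonical column from a vector of acceptable header spellings.
resolve_column <- function(columns, candidates, what, required = TRUE) {
  hit <- which(tolower(columns) %in% tolower(candidates))
  if (length(hit) == 0L) {
    if (!required) {
      return(NA_integer_)
    }
    abort(
      paste0(
        "required column '", what, "' not found; looked for: ",
        paste(candidates, collapse = ", ")
      ),
      class = "generisk_config_error"
    )
  }
  hit[[1L]]
}

`%||%` <- rlang::`%||%`

# Locale-independent character sort used everywhere node order matters.
sort_symbols <- function(x) sort(unique(x), method = "radix")

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(paste0(name, " must be a probability in [0, 1]"),
      class = "generisk_config_error"
    )
  }
}
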