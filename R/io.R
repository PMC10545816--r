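#' Deterministic per-gene seed
#'
#' Derives a 31-bit seed from a global seed and a gene name with a
#' polynomial rolling hash, so that a gene's training result does not
#' depend on which other genes are trained or on the worker count.
#'
#' @param seed Integer global seed.
#' @param name Character key (e.g. a gene name).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
gene_seed <- function(seed, name) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (code in utf8ToInt(as.character(name))) {
    h <- (h * 31 + code) %% mod
  }
  as.integer(h)
}

#' Read a spliced/unspliced dataset container
#'
#' Reads the CSV-pair dialect: a directory holding `u.csv` and `s.csv`
#' (cells x genes, first column `cell_id`) and optionally `obs.csv` with
#' per-cell metadata (labels, embedding coordinates as columns
#' `embedding_1`, `embedding_2`). Matrices are validated for matching
#' shapes, unique identifiers and the cells-as-rows orientation; a file
#' with genes as rows (detected through the `cell_id` header) is
#' transposed with a message.
#'
#' @param path Directory containing the CSV files.
#' @param dialect Only `"csv_pair"` is supported; requesting the HDF5
#'   dialects (`"loom"`, `"h5ad"`) raises an informative error.
#' @return A list with matrices `u`, `s`, data frame `obs` (or `NULL`),
#'   and `gene_names`.
#' @export
read_container <- function(path, dialect = c("csv_pair", "loom", "h5ad")) {
  dialect <- match.arg(dialect)
  if (dialect != "csv_pair") {
    stop(sprintf("dialect '%s' is not supported; ", dialect),
         "export the layers and provide the dataset as a CSV pair ",
         "(u.csv + s.csv)", call. = FALSE)
  }
  read_layer <- function(name) {
    f <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(f)) {
      have <- paste(list.files(path, pattern = "\\.csv$"), collapse = ", ")
      stop(sprintf("missing layer '%s' in %s (available: %s)",
                   name, path, have), call. = FALSE)
    }
    df <- read.csv(f, check.names = FALSE)
    if (names(df)[1] != "cell_id") {
      # genes-as-rows dialect: first column holds gene names
      message(sprintf("%s.csv: first column is not 'cell_id'; transposing",
                      name))
      m <- t(as.matrix(df[, -1, drop = FALSE]))
      colnames(m) <- df[[1]]
      return(m)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$cell_id
    m
  }
  u <- read_layer("u"); s <- read_layer("s")
  if (!all(dim(u) == dim(s)) || !identical(colnames(u), colnames(s))) {
    stop("shape or gene-name mismatch between u and s layers", call. = FALSE)
  }
  if (anyDuplicated(rownames(u)) || anyDuplicated(colnames(u))) {
    stop("cell and gene identifiers must be unique", call. = FALSE)
  }
  obs_file <- file.path(path, "obs.csv")
  obs <- if (file.exists(obs_file)) read.csv(obs_file) else NULL
  list(u = u, s = s, obs = obs, gene_names = colnames(u))
}

#' Pipeline configuration
#'
#' Bundles the training configuration with the projection and pseudotime
#' parameters of [run_pipeline()]. Unknown keys are rejected.
#'
#' @param ... Overrides for any of the defaults: all [train_config()]
#'   fields plus `neighbor_mode` (`"shared_spliced"`,
#'   `"shared_spliced_unspliced"` or `"embedding"`), `projection_k`,
#'   `sigma`, `grid_shape`, `n_steps`, `n_repeats`, `sway_sd`, `n_path`,
#'   `overlap_k`, `jobs`, `seed`.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(...) {
  defaults <- c(unclass(train_config()),
                list(neighbor_mode = "shared_spliced", projection_k = 200,
                     sigma = 0.05, grid_shape = c(30, 30), n_steps = 500,
                     n_repeats = 10, sway_sd = pi / 6, n_path = Inf,
                     overlap_k = 10, jobs = 1))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(modifyList(defaults, overrides), class = "run_config")
}

# the train_config embedded in a run_config
as_train_config <- function(config) {
  fields <- names(unclass(train_config()))
  do.call(train_config, config[fields])
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; stamped into every pipeline
#' output so that re-running with a changed configuration changes the
#' provenance.
#'
#' @param config Any serializable list.
#' @return A 32-character hash string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}
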