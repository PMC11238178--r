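#' Read connectome-style neuron and edge tables
#'
#' CSV formats: neuron tables have columns `id`, `class` and optionally
#' `glomerulus`, `ln_subclass`, `or_type`; edge tables have `pre_id`,
#' `post_id`, `synapse_count`.
#'
#' @param path CSV file path.
#' @return a `data.frame` ([neuron_table()]-shaped for neurons).
#' @export
read_neuron_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "class")
  if (!all(req %in% names(df))) {
    stop("neuron table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  for (col in c("glomerulus", "ln_subclass", "or_type")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  neuron_table(df$id, df$class, df$glomerulus, df$ln_subclass, df$or_type)
}

#' @rdname read_neuron_table
#' @export
read_edge_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("pre_id", "post_id", "synapse_count")
  if (!all(req %in% names(df))) {
    stop("edge table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read an OR response table from CSV
#'
#' Rows are OR types (first column `or_type`), remaining columns odorants,
#' values response intensities in `[0, 1]`.
#'
#' @param path CSV file path.
#' @param k,c,r_spo forwarded to [or_response_table()].
#' @return an [or_response_table()].
#' @export
read_or_table <- function(path, k = NULL, c = 192, r_spo = 8) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(df)[1] == "or_type")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$or_type
  or_response_table(m, k = k, c = c, r_spo = r_spo)
}

#' Read a glomerular innervation probability table from CSV
#'
#' First column `ln_subclass`, remaining columns glomeruli, values in
#' `[0, 1]`.
#'
#' @param path CSV file path.
#' @return numeric matrix, subclasses x glomeruli.
#' @export
read_innervation_probs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(df)[1] == "ln_subclass")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$ln_subclass
  stopifnot(all(m >= 0), all(m <= 1))
  m
}

#' Write / read a weight matrix as an edge-list CSV
#'
#' Columns `pre_id`, `post_id`, `weight`; only nonzero entries are stored.
#'
#' @param W sparse weight matrix with id dimnames.
#' @param path CSV file path.
#' @export
write_weight_csv <- function(W, path) {
  idx <- Matrix::which(W != 0, arr.ind = TRUE)
  df <- data.frame(pre_id = rownames(W)[idx[, 1]],
                   post_id = colnames(W)[idx[, 2]],
                   weight = W[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_csv
#' @param ids neuron ids fixing the matrix dimensions and order.
#' @export
read_weight_csv <- function(path, ids) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  edge_list_to_matrix(df, ids)
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized fields mirror the arguments of [run_simulation()] and the
#' experiment helpers (protocol kind, durations, seeds, inactivation list,
#' scaling overrides, arithmetic backend). Unknown fields are kept and
#' returned as-is.
#'
#' @param path file path ending in `.yaml`, `.yml`, or `.json`.
#' @return a named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext, call. = FALSE))
  if (!is.null(cfg$scaling)) cfg$scaling <- scaling_table(unlist(cfg$scaling))
  cfg
}
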