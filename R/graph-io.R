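write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(vapply(seq_len(nrow(m)), function(i) {
    paste(sprintf("%.17g", m[i, ]), collapse = "\t")
  }, character(1)), con)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Write a metabolic graph to a directory
#'
#' Stores the edge-weight and node-feature matrices as full-precision
#' TSV files plus a JSON metadata sidecar (subject id, label, feature
#' names, dimensions), so `read_graph(write_graph(g)) == g` exactly.
#'
#' @param graph a [metabolic_graph()].
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "metabolic_graph"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(graph$weights, file.path(path, "weights.tsv"))
  write_matrix_tsv(graph$node_features, file.path(path, "node_features.tsv"))
  meta <- list(
    subject_id = graph$subject_id,
    label = graph$label,
    n_nodes = nrow(graph$weights),
    n_node_features = ncol(graph$node_features),
    regions = rownames(graph$node_features),
    feature_names = colnames(graph$node_features)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a metabolic graph written by [write_graph()]
#'
#' Dimensions and graph invariants (symmetry, `[0, 1]` range, unit
#' diagonal) are enforced on read; a corrupted store is rejected.
#'
#' @param path directory produced by [write_graph()].
#' @return A [metabolic_graph()].
#' @export
read_graph <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  W <- read_matrix_tsv(file.path(path, "weights.tsv"))
  X <- read_matrix_tsv(file.path(path, "node_features.tsv"))
  if (nrow(W) != meta$n_nodes || ncol(W) != meta$n_nodes) {
    abort(sprintf("%s: weights matrix is %dx%d, metadata says %d nodes",
                  path, nrow(W), ncol(W), meta$n_nodes))
  }
  if (nrow(X) != meta$n_nodes || ncol(X) != meta$n_node_features) {
    abort(sprintf("%s: node-feature matrix dimensions disagree with metadata",
                  path))
  }
  check_symmetric(W, tol = 0)
  dimnames(W) <- list(meta$regions, meta$regions)
  dimnames(X) <- list(meta$regions, meta$feature_names)
  metabolic_graph(X, W, subject_id = meta$subject_id,
                  label = meta$label)
}
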