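#' Construct a metabolic graph record
#'
#' The container for a Regional Radiomics Similarity Network: node
#' features (one d-dimensional radiomic profile per region) and a
#' symmetric edge-weight matrix in `[0, 1]` with unit diagonal.
#'
#' @param node_features numeric matrix, regions x d.
#' @param weights symmetric numeric matrix in `[0, 1]`, unit diagonal.
#' @param subject_id subject identifier.
#' @param label optional diagnosis class.
#' @return An object of class `metabolic_graph`.
#' @export
metabolic_graph <- function(node_features, weights, subject_id = "subject",
                            label = NULL) {
  node_features <- as.matrix(node_features)
  weights <- as.matrix(weights)
  storage.mode(node_features) <- "double"
  storage.mode(weights) <- "double"
  check_symmetric(weights)
  if (nrow(weights) != nrow(node_features)) {
    abort("weights and node_features disagree on the number of regions")
  }
  if (min(weights) < -1e-12 || max(weights) > 1 + 1e-12) {
    abort("edge weights must lie in [0, 1]")
  }
  if (max(abs(diag(weights) - 1)) > 1e-12) {
    abort("edge-weight diagonal must be 1")
  }
  if (!is.null(label)) assert_classes(label)
  structure(
    list(subject_id = as.character(subject_id),
         node_features = node_features, weights = weights,
         label = if (is.null(label)) NULL else as.character(label)),
    class = "metabolic_graph"
  )
}

#' @export
print.metabolic_graph <- function(x, ...) {
  cat(sprintf("<metabolic_graph> subject %s: %d nodes, %d node features%s\n",
              x$subject_id, nrow(x$weights), ncol(x$node_features),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' Build a subject's Regional Radiomics Similarity Network
#'
#' Computes the pairwise Pearson correlation between every two regions'
#' normalized radiomic feature vectors and maps it onto `[0, 1]` edge
#' weights.  The default transform is the affine map `w = (r + 1) / 2`;
#' the diagonal is fixed at 1 so self-attention is never annihilated by
#' the connectivity mask downstream.  A region whose feature vector has
#' zero variance gets correlation 0 (weight 0.5) to every other region,
#' with a warning.
#'
#' @param table a normalized, feature-selected [radiomic_table()].
#' @param transform `"affine"` for `(r + 1) / 2` (default) or `"abs"`
#'   for `|r|`.
#' @return A [metabolic_graph()] with the table's label attached.
#' @export
build_r2sn <- function(table, transform = c("affine", "abs")) {
  stopifnot(inherits(table, "radiomic_table"))
  transform <- match.arg(transform)
  V <- table$values
  sds <- apply(V, 1L, sd)
  degenerate <- sds == 0
  R <- suppressWarnings(cor(t(V)))
  if (any(degenerate)) {
    warn(sprintf("zero-variance region(s) given correlation 0: %s",
                 paste(rownames(V)[degenerate], collapse = ", ")))
  }
  R[!is.finite(R)] <- 0
  R <- pmin(pmax(R, -1), 1)
  W <- switch(transform, affine = (R + 1) / 2, abs = abs(R))
  diag(W) <- 1
  W <- (W + t(W)) / 2
  metabolic_graph(V, W, subject_id = table$subject_id, label = table$label)
}

#' Group-average metabolic network
#'
#' Element-wise mean of the edge weights and node features of a set of
#' same-class graphs; the class label is preserved.  Means of `[0, 1]`
#' entries stay in `[0, 1]`, so the result is itself a valid graph.
#'
#' @param graphs non-empty list of [metabolic_graph()] with identical
#'   dimensions and the same class label.
#' @return A [metabolic_graph()] with subject id `"group_mean"`.
#' @export
group_average_network <- function(graphs) {
  if (!is.list(graphs) || length(graphs) == 0L) abort("need at least 1 graph")
  labels <- unique(vapply(graphs, function(g) g$label %||% NA_character_,
                          character(1)))
  if (length(labels) > 1L) abort("graphs must share a single class label")
  n <- nrow(graphs[[1L]]$weights)
  d <- ncol(graphs[[1L]]$node_features)
  W <- matrix(0, n, n); X <- matrix(0, n, d)
  for (g in graphs) {
    if (nrow(g$weights) != n || ncol(g$node_features) != d) {
      abort("graphs disagree on dimensions")
    }
    W <- W + g$weights
    X <- X + g$node_features
  }
  W <- W / length(graphs)
  X <- X / length(graphs)
  dimnames(W) <- dimnames(graphs[[1L]]$weights)
  dimnames(X) <- dimnames(graphs[[1L]]$node_features)
  metabolic_graph(X, W, subject_id = "group_mean",
                  label = if (is.na(labels)) NULL else labels)
}

#' Run the full R2SN pipeline over a cohort
#'
#' Fits feature selection on the cohort (unless one is supplied), then
#' normalizes each subject and builds its graph.
#'
#' @param cohort list of [radiomic_table()].
#' @param selection optional frozen `feature_selection` fit on a training
#'   cohort; fit on `cohort` when `NULL`.
#' @param threshold collinearity threshold when fitting.
#' @param transform edge transform passed to [build_r2sn()].
#' @return list with `graphs` and the `selection` used.
#' @export
cohort_to_graphs <- function(cohort, selection = NULL, threshold = 0.9,
                             transform = "affine") {
  if (is.null(selection)) {
    selection <- prune_collinear_features(cohort, threshold = threshold)
  }
  graphs <- lapply(cohort, function(t) {
    build_r2sn(minmax_normalize(t, selection), transform = transform)
  })
  list(graphs = graphs, selection = selection)
}
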