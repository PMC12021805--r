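# Interpretability: gradient-based node attribution, attention-based
# edge attribution, top-fraction edge retention and Jaccard contrasts.

#' Gradient-based node importance
#'
#' `I_node(i) = || d log p(y|G) / d x_i ||_2`: the L2 norm of the
#' gradient of the target class's log-probability with respect to each
#' node's input feature vector, computed with all dropout off.  The
#' default target is the predicted class; `target = "true"` uses the
#' graph's label.
#'
#' @param graph a [metabolic_graph()].
#' @param params a `gnn_params`.
#' @param target `"predicted"` or `"true"`.
#' @return Non-negative numeric vector, one score per node.
#' @export
node_importance <- function(graph, params, target = c("predicted", "true")) {
  target <- match.arg(target)
  config <- params$config
  masks <- default_masks(graph$weights, config)
  pl <- unpack_params(params)
  fw <- gnn_forward_cache(graph$node_features, graph$weights, masks, pl,
                          config, train = FALSE)
  y <- if (target == "true") {
    if (is.null(graph$label)) abort("graph has no label for target = 'true'")
    match(graph$label, PDS_CLASSES)
  } else {
    which.max(fw$head$probs)
  }
  # d log p_y / d logits = onehot(y) - p
  dlogits <- -fw$head$probs
  dlogits[y] <- dlogits[y] + 1
  bw <- gnn_backward(fw, pl, params$schema, dlogits)
  if (anyNA(bw$dX0) || !all(is.finite(bw$dX0))) {
    abort("non-finite node-importance gradient")
  }
  imp <- sqrt(rowSums(bw$dX0^2))
  names(imp) <- rownames(graph$node_features)
  imp
}

#' Attention-based edge importance
#'
#' `I_edge(i, j) = (1/L) sum_l A_{i,j}^l`, the arithmetic mean over
#' transformer layers of the head-averaged (pre-Hadamard, row-stochastic)
#' attention maps, symmetrized as `(M + M') / 2` since R2SN edges are
#' undirected.
#'
#' @param trace a `forward_trace` from [forward_gnn()].
#' @return Symmetric non-negative matrix of edge scores.
#' @export
edge_importance <- function(trace) {
  stopifnot(inherits(trace, "forward_trace"))
  L <- length(trace$attention)
  if (L == 0L) abort("trace holds no attention maps")
  M <- Reduce(`+`, lapply(trace$attention, function(heads) {
    if (length(heads) == 0L) abort("trace is missing per-head maps")
    Reduce(`+`, heads) / length(heads)
  })) / L
  (M + t(M)) / 2
}

#' Retain the top fraction of candidate edges
#'
#' Candidates are all `n (n - 1) / 2` unordered off-diagonal pairs; the
#' `ceiling(retain_fraction x candidates)` highest-scoring are kept.
#' Ties at the threshold are broken by lexicographic pair order, so the
#' retained set is deterministic.
#'
#' @param I_edge symmetric score matrix.
#' @param retain_fraction fraction of candidate pairs kept
#'   (default 0.15, i.e. 684 of 4560 pairs on a 96-node graph).
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per
#'   retained pair, ordered by decreasing score.
#' @export
retain_top_edges <- function(I_edge, retain_fraction = 0.15) {
  check_symmetric(I_edge)
  n <- nrow(I_edge)
  ut <- which(upper.tri(I_edge), arr.ind = TRUE)
  scores <- I_edge[upper.tri(I_edge)]
  m <- ceiling(retain_fraction * nrow(ut))
  ord <- order(-scores, ut[, 1], ut[, 2])
  keep <- ord[seq_len(m)]
  out <- cbind(i = ut[keep, 1], j = ut[keep, 2])
  rownames(out) <- NULL
  out
}

edge_key <- function(pairs) {
  if (length(pairs) == 0L) return(character(0))
  pairs <- as.matrix(pairs)
  lo <- pmin(pairs[, 1], pairs[, 2])
  hi <- pmax(pairs[, 1], pairs[, 2])
  paste(lo, hi, sep = "-")
}

#' Jaccard similarity of two edge sets
#'
#' `|A intersect B| / |A union B|` over unordered node pairs; two empty
#' sets are identical, hence similarity 1.
#'
#' @param set_a,set_b edge sets as two-column index matrices (or objects
#'   with a `retained_edges` field).
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_similarity <- function(set_a, set_b) {
  if (is.list(set_a) && !is.null(set_a$retained_edges)) {
    set_a <- set_a$retained_edges
  }
  if (is.list(set_b) && !is.null(set_b$retained_edges)) {
    set_b <- set_b$retained_edges
  }
  a <- unique(edge_key(set_a))
  b <- unique(edge_key(set_b))
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Map node importance scores to atlas regions
#'
#' @param I_node numeric vector of length 96 (atlas order).
#' @param atlas atlas tibble.
#' @return A tibble ranked by decreasing score (ties in stable atlas
#'   order): `rank`, `index`, `region`, `system`, `score`.
#' @export
map_to_rois <- function(I_node, atlas = default_atlas()) {
  validate_atlas(atlas)
  if (length(I_node) != nrow(atlas)) {
    abort(sprintf("importance vector has length %d, atlas has %d regions",
                  length(I_node), nrow(atlas)))
  }
  ord <- order(-I_node, atlas$index)
  tibble::tibble(rank = seq_along(ord), index = atlas$index[ord],
                 region = atlas$name[ord], system = atlas$system[ord],
                 score = as.numeric(I_node)[ord])
}

#' Explain one subject's prediction
#'
#' Combines gradient-based node importance, attention-based edge
#' importance, top-fraction edge retention and the ROI-mapped report.
#'
#' @param fit a `pds_gnn_fit` (or `gnn_params`).
#' @param graph a [metabolic_graph()].
#' @param target attribution target, `"predicted"` (default) or
#'   `"true"`.
#' @param retain_fraction fraction of edges retained.
#' @param atlas atlas for the ROI report.
#' @return A `pds_explanation`: `subject_id`, `predicted`, `probs`,
#'   `I_node`, `I_edge`, `retained_edges`, `roi_report`.
#' @export
explain_subject <- function(fit, graph, target = "predicted",
                            retain_fraction = 0.15,
                            atlas = default_atlas()) {
  params <- if (inherits(fit, "pds_gnn_fit")) fit$params else fit
  trace <- forward_gnn(graph, params)
  I_node <- node_importance(graph, params, target = target)
  I_edge <- edge_importance(trace)
  structure(
    list(subject_id = graph$subject_id,
         predicted = PDS_CLASSES[which.max(trace$probs)],
         probs = trace$probs,
         I_node = I_node, I_edge = I_edge,
         retained_edges = retain_top_edges(I_edge, retain_fraction),
         retain_fraction = retain_fraction,
         roi_report = map_to_rois(I_node, atlas)),
    class = "pds_explanation"
  )
}

#' @export
print.pds_explanation <- function(x, ...) {
  cat(sprintf("<pds_explanation> subject %s -> %s; top regions: %s\n",
              x$subject_id, x$predicted,
              paste(head(x$roi_report$region, 3), collapse = ", ")))
  invisible(x)
}

#' Group-level explanation for one class
#'
#' Averages node and edge importance over a class's graphs and retains
#' the consensus top edges from the mean edge-importance matrix.
#'
#' @param fit a `pds_gnn_fit`.
#' @param graphs list of graphs of a single class.
#' @param target attribution target.
#' @param retain_fraction fraction of edges retained.
#' @param atlas atlas tibble.
#' @return A `pds_group_explanation` with `class`, `mean_I_node`,
#'   `mean_I_edge`, `retained_edges`, `roi_report`, `n_subjects`.
#' @export
explain_group <- function(fit, graphs, target = "predicted",
                          retain_fraction = 0.15,
                          atlas = default_atlas()) {
  stopifnot(length(graphs) >= 1L)
  labels <- unique(vapply(graphs, function(g) g$label %||% NA_character_,
                          character(1)))
  if (length(labels) != 1L) abort("graphs must come from a single class")
  exps <- lapply(graphs, function(g) {
    explain_subject(fit, g, target = target,
                    retain_fraction = retain_fraction, atlas = atlas)
  })
  mean_node <- Reduce(`+`, lapply(exps, `[[`, "I_node")) / length(exps)
  mean_edge <- Reduce(`+`, lapply(exps, `[[`, "I_edge")) / length(exps)
  structure(
    list(class = labels, mean_I_node = mean_node, mean_I_edge = mean_edge,
         retained_edges = retain_top_edges(mean_edge, retain_fraction),
         roi_report = map_to_rois(mean_node, atlas),
         n_subjects = length(graphs)),
    class = "pds_group_explanation"
  )
}

#' Class-wise explanations and their Jaccard contrast matrix
#'
#' Builds a group explanation per class and the symmetric matrix of
#' Jaccard similarities between the classes' retained edge sets --
#' disease-specific connectivity patterns should show low cross-class
#' overlap.
#'
#' @param fit a `pds_gnn_fit`.
#' @param graphs list of labelled graphs (several classes).
#' @param ... passed to [explain_group()].
#' @return list with `groups` (named list of group explanations) and
#'   `jaccard` (symmetric matrix).
#' @export
explain_classes <- function(fit, graphs, ...) {
  labels <- vapply(graphs, function(g) g$label %||% NA_character_,
                   character(1))
  classes <- intersect(PDS_CLASSES, unique(labels))
  groups <- lapply(setNames(classes, classes), function(cl) {
    explain_group(fit, graphs[labels == cl], ...)
  })
  J <- matrix(1, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (a in seq_along(classes)) {
    for (b in seq_along(classes)) {
      if (a < b) {
        J[a, b] <- J[b, a] <- jaccard_similarity(groups[[a]], groups[[b]])
      }
    }
  }
  list(groups = groups, jaccard = J)
}

#' Write an explanation to TSV reports
#'
#' Node report (`rank`, `index`, `region`, `system`, `score`) and the
#' retained edge pair list.
#'
#' @param x a `pds_explanation` or `pds_group_explanation`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_explanation <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$roi_report, file.path(dir, "node_importance.tsv"))
  readr::write_tsv(tibble::as_tibble(as.data.frame(x$retained_edges)),
                   file.path(dir, "retained_edges.tsv"))
  invisible(dir)
}
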