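#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_tile labs theme_minimal scale_fill_viridis_c scale_fill_gradient
#'   coord_flip facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Training curves for a fit
#'
#' Training and validation loss (and accuracy) per epoch.
#'
#' @param object a `pds_gnn_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pds_gnn_fit <- function(object, ...) {
  h <- object$history |>
    dplyr::select("epoch", train = "train_loss", validation = "val_loss") |>
    tidyr::pivot_longer(-"epoch", names_to = "set", values_to = "loss")
  ggplot(h, aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    geom_line() +
    labs(x = "epoch", y = "loss", colour = NULL,
         title = "Training and validation loss") +
    theme_minimal()
}

#' Top node importances of an explanation
#'
#' @param object a `pds_explanation` or `pds_group_explanation`.
#' @param top_n number of regions shown.
#' @param ... unused.
#' @return A ggplot bar chart of the highest-scoring regions.
#' @export
autoplot.pds_explanation <- function(object, top_n = 20, ...) {
  r <- head(object$roi_report, top_n)
  ggplot(r, aes(x = stats::reorder(.data$region, .data$score),
                y = .data$score, fill = .data$system)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "node importance", fill = NULL,
         title = sprintf("Gradient node importance (subject %s)",
                         object$subject_id)) +
    theme_minimal()
}

#' @rdname autoplot.pds_explanation
#' @export
autoplot.pds_group_explanation <- function(object, top_n = 20, ...) {
  r <- head(object$roi_report, top_n)
  ggplot(r, aes(x = stats::reorder(.data$region, .data$score),
                y = .data$score, fill = .data$system)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "mean node importance", fill = NULL,
         title = sprintf("Group node importance (%s, n = %d)",
                         object$class, object$n_subjects)) +
    theme_minimal()
}

#' Heat map of an edge-weight or edge-importance matrix
#'
#' @param M symmetric matrix (e.g. `metabolic_graph$weights` or
#'   `I_edge`).
#' @param title plot title.
#' @return A ggplot tile map.
#' @export
plot_adjacency <- function(M, title = "Edge weights") {
  df <- tidyr::expand_grid(i = seq_len(nrow(M)), j = seq_len(ncol(M)))
  df$w <- as.vector(M[cbind(df$i, df$j)])
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$w)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = NULL, title = title) +
    theme_minimal()
}

#' Per-class metric bars
#'
#' @param object a `pds_metrics`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pds_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("class", "recall", "precision", "f1")],
    -"class", names_to = "metric", values_to = "percent")
  ggplot(long, aes(x = .data$class, y = .data$percent,
                   fill = .data$metric)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "percent", fill = NULL,
         title = "Per-class recall / precision / F1") +
    theme_minimal()
}
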