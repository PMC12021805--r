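#' Apply the stochastic regularization suite to a batch of graphs
#'
#' In training mode: (1) whole node-feature rows are zeroed with
#' probability `node_feature_dropout` and the surviving rows rescaled by
#' `1 / (1 - p)`; (2) a random `edge_noise_fraction` subset of
#' off-diagonal (unordered) edges receives additive Gaussian noise of sd
#' `edge_noise_sigma`, after which weights are clipped back to `[0, 1]`
#' and kept symmetric (the diagonal is untouched).  Attention dropout and
#' fully-connected dropout live inside the forward pass itself.  In eval
#' mode the batch is returned unchanged.
#'
#' @param graphs list of [metabolic_graph()].
#' @param config a [train_config()].
#' @param mode `"train"` or `"eval"`.
#' @return The (possibly perturbed) list of graphs.
#' @export
apply_regularization <- function(graphs, config, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  if (mode == "eval") return(graphs)
  p <- config$node_feature_dropout
  fr <- config$edge_noise_fraction
  sg <- config$edge_noise_sigma
  lapply(graphs, function(g) {
    n <- nrow(g$weights)
    if (p > 0) {
      keep <- runif(n) >= p
      g$node_features <- g$node_features * (keep / (1 - p))
    }
    if (fr > 0 && sg > 0) {
      ut <- which(upper.tri(g$weights))
      m <- length(ut)
      hit <- ut[runif(m) < fr]
      if (length(hit)) {
        W <- g$weights
        W[hit] <- pmin(pmax(W[hit] + rnorm(length(hit), 0, sg), 0), 1)
        W[lower.tri(W)] <- t(W)[lower.tri(W)]
        g$weights <- W
      }
    }
    g
  })
}
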