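# Exported single-operation surfaces over the forward core.  These run
# one component at a time on explicit inputs, which is how the unit
# tests compare each block against brute-force oracles.

#' Gated fusion of node features with a structure token
#'
#' `g_i = sigmoid(W_g [x_i || s])`, `x~_i = g_i * x_i + (1 - g_i) * s`,
#' elementwise.  The learnable token `s` injects a layer-wide summary
#' into every node, with the gate controlling cross-scale information
#' flow.
#'
#' @param X node features, n x d.
#' @param s structure token, length d.
#' @param W_g gate projection, 2d x d.
#' @return Fused features, n x d.
#' @export
gated_structure_fusion <- function(X, s, W_g) {
  n <- nrow(X); d <- ncol(X)
  stopifnot(length(s) == d, nrow(W_g) == 2 * d, ncol(W_g) == d)
  Smat <- matrix(s, n, d, byrow = TRUE)
  G <- sigmoid(cbind(X, Smat) %*% W_g)
  G * X + (1 - G) * Smat
}

#' Position-wise feed-forward network
#'
#' `FFN(x) = W_2 GELU(W_1 x + b_1) + b_2`, applied row-wise with the
#' exact Gaussian-CDF GELU.
#'
#' @param X input, n x d.
#' @param W_1 first projection, d_ffn x d.
#' @param b_1 first bias, length d_ffn.
#' @param W_2 second projection, d x d_ffn.
#' @param b_2 second bias, length d.
#' @return n x d matrix.
#' @export
feed_forward <- function(X, W_1, b_1, W_2, b_2) {
  n <- nrow(X)
  gelu(X %*% t(W_1) + rep(b_1, each = n)) %*% t(W_2) + rep(b_2, each = n)
}

#' Connectivity-masked multi-head graph attention
#'
#' Per head, scaled dot-product attention `softmax(QK'/sqrt(d_k))` is
#' computed over the keys (masked-out entries set to `-Inf` before the
#' softmax), then multiplied elementwise by the graph's edge weights so
#' connectivity strength attenuates message passing; head outputs are
#' concatenated and projected back to the model dimension.
#'
#' @param X node features (already fused), n x d_model.
#' @param weights edge-weight matrix, n x n.
#' @param params a `gnn_params`.
#' @param layer layer index (1-based).
#' @param mask optional logical n x n mask (`NULL` = global attention).
#' @return list with `output` (n x d_model) and `attention` (list of
#'   per-head pre-Hadamard attention matrices, rows summing to 1).
#' @export
graph_attention <- function(X, weights, params, layer, mask = NULL) {
  stopifnot(inherits(params, "gnn_params"))
  if (anyNA(X) || !all(is.finite(X)) || !all(is.finite(weights))) {
    abort("non-finite inputs to graph_attention")
  }
  pl <- unpack_params(params)
  att <- attention_core(X, weights, mask, pl$layers[[layer]],
                        params$config, train = FALSE)
  list(output = att$Xatt, attention = lapply(att$heads, `[[`, "A"))
}

#' One graph-transformer layer
#'
#' Composition: gated structure fusion, then attention and the
#' feed-forward network on the fused features, then a single
#' post-LayerNorm over the three-term sum
#' `LayerNorm(X + Attention(X) + FFN(X))`.
#'
#' @param X layer input, n x d_model.
#' @param graph a [metabolic_graph()] supplying edge weights.
#' @param params a `gnn_params`.
#' @param layer layer index.
#' @param mask optional attention mask.
#' @return The layer output, n x d_model.
#' @export
transformer_layer <- function(X, graph, params, layer, mask = NULL) {
  stopifnot(inherits(params, "gnn_params"))
  pl <- unpack_params(params)
  layer_forward(X, graph$weights, mask, pl$layers[[layer]],
                params$config, train = FALSE)$Xout
}
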