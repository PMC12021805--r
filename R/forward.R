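# Pure-R reference implementation of the graph-transformer forward pass.
# It caches every intermediate needed by the analytic backward pass in
# backward.R; an equivalent compiled fast path (src/gnn.cpp) is used by
# the training loop and is equivalence-tested against this one.

LN_EPS <- 1e-5

# row-wise LayerNorm; returns output plus backward cache
layer_norm_rows <- function(R, g, b) {
  n <- nrow(R)
  mu <- rowMeans(R)
  Rc <- R - mu
  v <- rowMeans(Rc * Rc)
  inv <- 1 / sqrt(v + LN_EPS)
  Xhat <- Rc * inv
  Y <- Xhat * rep(g, each = n) + rep(b, each = n)
  list(Y = Y, Xhat = Xhat, inv = inv)
}

layer_norm_vec <- function(x, g, b) {
  mu <- mean(x)
  xc <- x - mu
  v <- mean(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(y = g * xhat + b, xhat = xhat, inv = inv)
}

#' TopK edge sparsification mask
#'
#' For each node, the `k` largest-weight neighbors (self excluded) are
#' kept; the mask is symmetrized by union and the diagonal is always
#' kept.  Ties are broken in favor of the lower node index, so the mask
#' is fully deterministic.
#'
#' @param weights symmetric edge-weight matrix in `[0, 1]`.
#' @param k neighbors kept per node; `k >= n - 1` keeps everything
#'   (with a warning when `k >= n`).
#' @return A logical matrix of the same dimension.
#' @export
topk_sparsify <- function(weights, k) {
  check_symmetric(weights)
  n <- nrow(weights)
  if (k >= n) {
    warn(sprintf("k = %d >= %d nodes; keeping the full graph", k, n))
    return(matrix(TRUE, n, n))
  }
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    w <- weights[i, ]
    w[i] <- -Inf
    # order by decreasing weight, lower index first on ties
    ord <- order(-w, seq_len(n))
    mask[i, ord[seq_len(k)]] <- TRUE
  }
  mask <- mask | t(mask)
  diag(mask) <- TRUE
  mask
}

# core attention for one layer; X is the fused input
attention_core <- function(Xf, Wedge, mask, lp, config, train = FALSE) {
  n <- nrow(Xf); H <- config$n_heads
  dk <- config$d_k
  p_att <- if (train) config$attention_dropout else 0
  heads <- vector("list", H)
  for (h in seq_len(H)) {
    Q <- Xf %*% lp$Wq[[h]]
    K <- Xf %*% lp$Wk[[h]]
    V <- Xf %*% lp$Wv[[h]]
    Sc <- tcrossprod(Q, K) / sqrt(dk)
    if (!is.null(mask)) Sc[!mask] <- -Inf
    A <- softmax_rows(Sc)
    if (p_att > 0) {
      D <- matrix(runif(n * n) >= p_att, n, n) / (1 - p_att)
      Ad <- A * D
    } else {
      D <- NULL
      Ad <- A
    }
    At <- Ad * Wedge
    rs <- NULL
    if (config$renormalize_attention) {
      rs <- pmax(rowSums(At), 1e-12)
      At <- At / rs
    }
    heads[[h]] <- list(Q = Q, K = K, V = V, A = A, D = D, At = At, rs = rs,
                       O = At %*% V)
  }
  Ocat <- do.call(cbind, lapply(heads, `[[`, "O"))
  list(heads = heads, Ocat = Ocat, Xatt = Ocat %*% lp$Wo)
}

# one transformer layer with cache; order: gated fusion -> attention and
# FFN on the fused features -> single post-LayerNorm over the 3-term sum
layer_forward <- function(Xin, Wedge, mask, lp, config, train = FALSE) {
  n <- nrow(Xin); d <- config$d_model
  Smat <- matrix(lp$s, n, d, byrow = TRUE)
  Cc <- cbind(Xin, Smat)
  U <- Cc %*% lp$Wg
  G <- sigmoid(U)
  Xf <- G * Xin + (1 - G) * Smat
  att <- attention_core(Xf, Wedge, mask, lp, config, train)
  H1 <- Xf %*% t(lp$W1) + rep(lp$b1, each = n)
  Hg <- gelu(H1)
  Ff <- Hg %*% t(lp$W2) + rep(lp$b2, each = n)
  R <- Xin + att$Xatt + Ff
  ln <- layer_norm_rows(R, lp$lng, lp$lnb)
  list(Xout = ln$Y, Xin = Xin, Smat = Smat, Cc = Cc, G = G, Xf = Xf,
       att = att, H1 = H1, Hg = Hg, ln = ln)
}

# classification head with cache
head_forward <- function(hcat, hp, config, train = FALSE) {
  p_fc <- if (train) config$head_dropout else 0
  dropmask <- function(m) {
    if (p_fc > 0) (runif(m) >= p_fc) / (1 - p_fc) else rep(1, m)
  }
  ln0 <- layer_norm_vec(hcat, hp$ln0g, hp$ln0b)
  m0 <- dropmask(length(hcat)); d0 <- ln0$y * m0
  a_pre <- as.vector(hp$Wa %*% d0) + hp$ba
  a_act <- gelu(a_pre)
  ln1 <- layer_norm_vec(a_act, hp$ln1g, hp$ln1b)
  m1 <- dropmask(length(a_act)); d1 <- ln1$y * m1
  b_pre <- as.vector(hp$Wb %*% d1) + hp$bb
  b_act <- gelu(b_pre)
  ln2 <- layer_norm_vec(b_act, hp$ln2g, hp$ln2b)
  m2 <- dropmask(length(b_act)); d2 <- ln2$y * m2
  logits <- as.vector(hp$Wc %*% d2) + hp$bc
  list(logits = logits, probs = softmax_vec(logits),
       ln0 = ln0, m0 = m0, d0 = d0, a_pre = a_pre, a_act = a_act,
       ln1 = ln1, m1 = m1, d1 = d1, b_pre = b_pre, b_act = b_act,
       ln2 = ln2, m2 = m2, d2 = d2)
}

# SupCon projection head with cache
proj_forward <- function(hcat, pp) {
  p_pre <- as.vector(pp$W1 %*% hcat) + pp$b1
  p_act <- gelu(p_pre)
  q <- as.vector(pp$W2 %*% p_act) + pp$b2
  nrm <- sqrt(sum(q * q))
  z <- q / max(nrm, 1e-12)
  list(z = z, q = q, nrm = max(nrm, 1e-12), p_pre = p_pre, p_act = p_act)
}

# full forward with cache (internal); masks is a list of per-layer
# logical matrices or NULLs (NULL = global attention)
gnn_forward_cache <- function(X0, Wedge, masks, pl, config, train = FALSE,
                              with_proj = FALSE) {
  if (anyNA(X0) || !all(is.finite(X0))) abort("non-finite node features")
  n <- nrow(X0)
  layers <- vector("list", config$n_layers)
  hpool <- vector("list", config$n_layers)
  pool_idx <- vector("list", config$n_layers)
  X <- X0
  for (l in seq_len(config$n_layers)) {
    layers[[l]] <- layer_forward(X, Wedge, masks[[l]], pl$layers[[l]],
                                 config, train)
    X <- layers[[l]]$Xout
    idx <- max.col(t(X), ties.method = "first")
    pool_idx[[l]] <- idx
    hpool[[l]] <- X[cbind(idx, seq_len(ncol(X)))]
  }
  hcat <- unlist(hpool, use.names = FALSE)
  head <- head_forward(hcat, pl$head, config, train)
  proj <- if (with_proj) proj_forward(hcat, pl$proj) else NULL
  list(X0 = X0, Wedge = Wedge, masks = masks, layers = layers,
       hpool = hpool, pool_idx = pool_idx, hcat = hcat, head = head,
       proj = proj, config = config, train = train)
}

#' Forward pass of the graph transformer
#'
#' Runs a graph through the stacked attention layers (inference mode:
#' all dropout off), max-pools each layer's node representations,
#' concatenates them and applies the MLP head.  Attention maps are cached
#' for the explainability module.
#'
#' @param graph a [metabolic_graph()].
#' @param params a `gnn_params` from [init_params()] or training.
#' @param masks optional list of per-layer attention masks; computed from
#'   the config's `topk_neighbors` / `mask_layers` when `NULL`.
#' @return A `forward_trace`: per-layer node representations
#'   `node_repr`, per-layer per-head attention maps `attention`
#'   (pre-Hadamard row-stochastic matrices), per-layer pooled vectors
#'   `h_pool`, their concatenation `h_concat`, `logits` and class
#'   `probs`.
#' @export
forward_gnn <- function(graph, params, masks = NULL) {
  stopifnot(inherits(graph, "metabolic_graph"), inherits(params, "gnn_params"))
  config <- params$config
  if (nrow(graph$weights) != config$n_nodes ||
      ncol(graph$node_features) != config$d_model) {
    abort(sprintf("graph is %d nodes x %d features but config wants %d x %d",
                  nrow(graph$weights), ncol(graph$node_features),
                  config$n_nodes, config$d_model))
  }
  if (is.null(masks)) masks <- default_masks(graph$weights, config)
  pl <- unpack_params(params)
  fw <- gnn_forward_cache(graph$node_features, graph$weights, masks, pl,
                          config, train = FALSE)
  new_forward_trace(fw, graph)
}

new_forward_trace <- function(fw, graph) {
  structure(
    list(subject_id = graph$subject_id,
         label = graph$label,
         node_repr = lapply(fw$layers, `[[`, "Xout"),
         attention = lapply(fw$layers, function(L) {
           lapply(L$att$heads, `[[`, "A")
         }),
         h_pool = fw$hpool,
         h_concat = fw$hcat,
         logits = fw$head$logits,
         probs = setNames(fw$head$probs, PDS_CLASSES[seq_along(fw$head$probs)]),
         cache = fw),
    class = "forward_trace"
  )
}

#' @export
print.forward_trace <- function(x, ...) {
  cat(sprintf("<forward_trace> subject %s: p = (%s)\n", x$subject_id,
              paste(sprintf("%s %.3f", names(x$probs), x$probs),
                    collapse = ", ")))
  invisible(x)
}

# per-layer masks from the config: NULL = global attention
default_masks <- function(weights, config) {
  tk <- NULL
  lapply(seq_len(config$n_layers), function(l) {
    if (!config$mask_layers[l]) return(NULL)
    if (is.null(tk)) tk <<- topk_sparsify(weights, config$topk_neighbors)
    tk
  })
}
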