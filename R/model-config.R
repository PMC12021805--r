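#' Graph-transformer architecture configuration
#'
#' Dimensions follow the published architecture: 96 nodes carrying
#' 36-dimensional radiomic feature vectors, three stacked transformer
#' layers with 4-head attention (key dim 24, value dim 32), a 144-unit
#' position-wise feed-forward network, element-wise max pooling per layer
#' concatenated to a 108-dim graph representation, and a 128-64-3 MLP
#' head.  `topk_neighbors` controls the TopK edge sparsification used to
#' localize attention; by default layer 1 attends globally and layers 2-3
#' attend within the TopK subgraph.
#'
#' @param n_nodes number of graph nodes (atlas regions).
#' @param d_model node feature dimension.
#' @param n_layers number of transformer layers.
#' @param n_heads attention heads per layer.
#' @param d_k per-head query/key dimension.
#' @param d_v per-head value dimension.
#' @param d_ffn hidden width of the feed-forward network.
#' @param head_dims hidden widths of the classification head.
#' @param n_classes number of diagnostic classes.
#' @param head_dropout dropout probability in the classification head
#'   (training mode only).
#' @param attention_dropout dropout probability on attention weights
#'   (training mode only).
#' @param topk_neighbors neighbors kept per node by TopK sparsification.
#' @param mask_layers logical vector, one per layer: whether that layer's
#'   attention is restricted to the TopK subgraph.
#' @param renormalize_attention if `TRUE`, rows of the connectivity-masked
#'   attention are renormalized to sum to 1; with the default `FALSE` the
#'   Hadamard product deliberately attenuates attention by connectivity
#'   strength.
#' @param seed integer seed for parameter initialization.
#' @return A `model_config` list; `pool_concat_dim` is derived as
#'   `n_layers * d_model`.
#' @export
model_config <- function(n_nodes = 96L, d_model = 36L, n_layers = 3L,
                         n_heads = 4L, d_k = 24L, d_v = 32L, d_ffn = 144L,
                         head_dims = c(128L, 64L), n_classes = 3L,
                         head_dropout = 0.3, attention_dropout = 0.1,
                         topk_neighbors = 8L,
                         mask_layers = NULL,
                         renormalize_attention = FALSE,
                         seed = 1L) {
  if (is.null(mask_layers)) {
    mask_layers <- c(FALSE, rep(TRUE, max(0L, n_layers - 1L)))
  }
  if (length(mask_layers) != n_layers) {
    abort("mask_layers must have one entry per layer")
  }
  dims <- c(n_nodes = n_nodes, d_model = d_model, n_layers = n_layers,
            n_heads = n_heads, d_k = d_k, d_v = d_v, d_ffn = d_ffn,
            n_classes = n_classes)
  if (any(dims <= 0)) abort("all dimensions must be positive")
  structure(
    list(n_nodes = as.integer(n_nodes), d_model = as.integer(d_model),
         n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
         d_k = as.integer(d_k), d_v = as.integer(d_v),
         d_ffn = as.integer(d_ffn), head_dims = as.integer(head_dims),
         n_classes = as.integer(n_classes),
         pool_concat_dim = as.integer(n_layers * d_model),
         head_dropout = head_dropout,
         attention_dropout = attention_dropout,
         topk_neighbors = as.integer(topk_neighbors),
         mask_layers = as.logical(mask_layers),
         renormalize_attention = isTRUE(renormalize_attention),
         proj_dims = c(64L, 32L),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

# Parameter catalogue: one row per learnable tensor, with its shape and
# offset into the flat parameter vector.  Order is fixed by construction
# so checkpoints, Adam state and C++ offsets all agree.
param_schema <- function(config) {
  d <- config$d_model; dk <- config$d_k; dv <- config$d_v
  H <- config$n_heads; dffn <- config$d_ffn; P <- config$pool_concat_dim
  hd <- config$head_dims; C <- config$n_classes; pj <- config$proj_dims
  rows <- list()
  add <- function(name, nr, nc = 1L) {
    rows[[length(rows) + 1L]] <<- list(name = name, nr = as.integer(nr),
                                       nc = as.integer(nc))
  }
  for (l in seq_len(config$n_layers)) {
    p <- function(x) sprintf("L%d.%s", l, x)
    for (h in seq_len(H)) add(p(sprintf("Wq%d", h)), d, dk)
    for (h in seq_len(H)) add(p(sprintf("Wk%d", h)), d, dk)
    for (h in seq_len(H)) add(p(sprintf("Wv%d", h)), d, dv)
    add(p("Wo"), H * dv, d)
    add(p("s"), d)
    add(p("Wg"), 2L * d, d)
    add(p("W1"), dffn, d); add(p("b1"), dffn)
    add(p("W2"), d, dffn); add(p("b2"), d)
    add(p("lng"), d); add(p("lnb"), d)
  }
  add("head.ln0g", P); add("head.ln0b", P)
  add("head.Wa", hd[1], P); add("head.ba", hd[1])
  add("head.ln1g", hd[1]); add("head.ln1b", hd[1])
  add("head.Wb", hd[2], hd[1]); add("head.bb", hd[2])
  add("head.ln2g", hd[2]); add("head.ln2b", hd[2])
  add("head.Wc", C, hd[2]); add("head.bc", C)
  add("proj.W1", pj[1], P); add("proj.b1", pj[1])
  add("proj.W2", pj[2], pj[1]); add("proj.b2", pj[2])
  schema <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r$name, nr = r$nr, nc = r$nc)
  }))
  schema$size <- schema$nr * schema$nc
  schema$offset <- cumsum(c(0L, schema$size[-nrow(schema)]))
  schema
}

#' Initialize model parameters
#'
#' Deterministic given the config seed: weight matrices use Glorot-normal
#' initialization (sd `sqrt(2 / (fan_in + fan_out))`), biases start at 0,
#' LayerNorm scales at 1 and structure tokens from N(0, 0.02).
#'
#' @param config a [model_config()].
#' @return A `gnn_params` object: flat parameter vector `theta` plus the
#'   shape schema and the config.
#' @export
init_params <- function(config) {
  schema <- param_schema(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  theta <- numeric(sum(schema$size))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]; nr <- schema$nr[i]; nc <- schema$nc[i]
    idx <- schema$offset[i] + seq_len(schema$size[i])
    theta[idx] <- if (grepl("\\.ln[0-9]?g$", nm)) {
      1
    } else if (grepl("(\\.b[0-9abc]$)|(ln[0-9]?b$)", nm)) {
      0
    } else if (grepl("\\.s$", nm)) {
      rnorm(nr * nc, 0, 0.02)
    } else {
      rnorm(nr * nc, 0, sqrt(2 / (nr + nc)))
    }
  }
  structure(list(theta = theta, schema = schema, config = config,
                 seed = config$seed),
            class = "gnn_params")
}

#' @export
print.gnn_params <- function(x, ...) {
  cat(sprintf("<gnn_params> %d tensors, %d parameters (seed %d)\n",
              nrow(x$schema), length(x$theta), x$seed))
  invisible(x)
}

#' Fetch one tensor from a parameter vector by schema name
#'
#' @param params a `gnn_params`.
#' @param name schema name, e.g. `"L1.Wq1"`, `"head.Wa"`.
#' @return The tensor as a matrix (or vector for column shapes).
#' @export
par_get <- function(params, name) {
  i <- match(name, params$schema$name)
  if (is.na(i)) abort(sprintf("unknown parameter '%s'", name))
  s <- params$schema[i, ]
  m <- matrix(params$theta[s$offset + seq_len(s$size)], s$nr, s$nc)
  if (s$nc == 1L) drop(m) else m
}

#' Replace one tensor in a parameter vector by schema name
#'
#' @inheritParams par_get
#' @param value replacement values with the tensor's shape.
#' @return The modified `gnn_params`.
#' @export
par_set <- function(params, name, value) {
  i <- match(name, params$schema$name)
  if (is.na(i)) abort(sprintf("unknown parameter '%s'", name))
  s <- params$schema[i, ]
  stopifnot(length(value) == s$size)
  params$theta[s$offset + seq_len(s$size)] <- as.numeric(value)
  params
}

# unpack the flat vector into nested lists once per forward/backward call
unpack_params <- function(params) {
  cfg <- params$config
  H <- cfg$n_heads
  g <- function(n) par_get(params, n)
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    p <- function(x) sprintf("L%d.%s", l, x)
    list(
      Wq = lapply(seq_len(H), function(h) g(p(sprintf("Wq%d", h)))),
      Wk = lapply(seq_len(H), function(h) g(p(sprintf("Wk%d", h)))),
      Wv = lapply(seq_len(H), function(h) g(p(sprintf("Wv%d", h)))),
      Wo = g(p("Wo")), s = g(p("s")), Wg = g(p("Wg")),
      W1 = g(p("W1")), b1 = g(p("b1")), W2 = g(p("W2")), b2 = g(p("b2")),
      lng = g(p("lng")), lnb = g(p("lnb"))
    )
  })
  head <- list(ln0g = g("head.ln0g"), ln0b = g("head.ln0b"),
               Wa = g("head.Wa"), ba = g("head.ba"),
               ln1g = g("head.ln1g"), ln1b = g("head.ln1b"),
               Wb = g("head.Wb"), bb = g("head.bb"),
               ln2g = g("head.ln2g"), ln2b = g("head.ln2b"),
               Wc = g("head.Wc"), bc = g("head.bc"))
  proj <- list(W1 = g("proj.W1"), b1 = g("proj.b1"),
               W2 = g("proj.W2"), b2 = g("proj.b2"))
  list(layers = layers, head = head, proj = proj)
}

# save/restore the global RNG state so seeded helpers do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write model parameters to a checkpoint file
#'
#' Single-file JSON archive of the flat parameter vector (printed with 17
#' significant digits, so doubles round-trip exactly), the architecture
#' config and the init seed.
#'
#' @param params a `gnn_params`.
#' @param path output file.
#' @param metadata optional named list stored alongside.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(params, path, metadata = NULL) {
  stopifnot(inherits(params, "gnn_params"))
  cfg <- unclass(params$config)
  obj <- list(format = "pdsgraph-checkpoint-v1",
              config = cfg,
              seed = params$seed,
              metadata = metadata,
              theta = sprintf("%.17g", params$theta))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Read a checkpoint written by [write_checkpoint()]
#'
#' @param path checkpoint file.
#' @return A `gnn_params` with attribute `"metadata"`.
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pdsgraph-checkpoint-v1")) {
    abort(sprintf("%s: not a pdsgraph checkpoint", path))
  }
  cfg <- obj$config
  config <- model_config(
    n_nodes = cfg$n_nodes, d_model = cfg$d_model, n_layers = cfg$n_layers,
    n_heads = cfg$n_heads, d_k = cfg$d_k, d_v = cfg$d_v, d_ffn = cfg$d_ffn,
    head_dims = cfg$head_dims, n_classes = cfg$n_classes,
    head_dropout = cfg$head_dropout,
    attention_dropout = cfg$attention_dropout,
    topk_neighbors = cfg$topk_neighbors, mask_layers = cfg$mask_layers,
    renormalize_attention = cfg$renormalize_attention, seed = cfg$seed
  )
  params <- init_params(config)
  theta <- as.numeric(obj$theta)
  if (length(theta) != length(params$theta)) {
    abort(sprintf("%s: checkpoint has %d parameters, config implies %d",
                  path, length(theta), length(params$theta)))
  }
  params$theta <- theta
  attr(params, "metadata") <- obj$metadata
  params
}
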