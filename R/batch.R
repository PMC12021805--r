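# Batch forward/backward over a list of graphs, through either the
# pure-R reference implementation or the compiled fast path.  Both
# return the same structure and are equivalence-tested.

config_dims <- function(config) {
  c(n_layers = config$n_layers, n_heads = config$n_heads,
    n_nodes = config$n_nodes, d_model = config$d_model,
    d_k = config$d_k, d_v = config$d_v, d_ffn = config$d_ffn,
    n_classes = config$n_classes,
    hd1 = config$head_dims[1], hd2 = config$head_dims[2],
    pj1 = config$proj_dims[1], pj2 = config$proj_dims[2])
}

# Xs/Ws: lists of matrices; masks: list (per graph) of lists (per layer,
# NULL = global); yidx: integer class indices (NA allowed when
# want_grad = FALSE and no supcon)
batch_grad <- function(params, Xs, Ws, masks, yidx, tconf,
                       train = FALSE, want_grad = TRUE,
                       with_supcon = TRUE,
                       backend = c("compiled", "reference")) {
  backend <- match.arg(backend)
  config <- params$config
  B <- length(Xs)
  if (backend == "compiled") {
    res <- cpp_batch_grad(
      Xs, Ws, masks, as.integer(yidx), params$theta,
      as.integer(config_dims(config)) |> setNames(names(config_dims(config))),
      train, if (train) config$attention_dropout else 0,
      if (train) config$head_dropout else 0,
      config$renormalize_attention, want_grad, with_supcon,
      tconf$temperature, tconf$lambda_supcon
    )
    return(res)
  }
  pl <- unpack_params(params)
  caches <- vector("list", B)
  probs <- matrix(NA_real_, B, config$n_classes)
  ce <- 0
  for (b in seq_len(B)) {
    caches[[b]] <- gnn_forward_cache(Xs[[b]], Ws[[b]], masks[[b]], pl,
                                     config, train = train,
                                     with_proj = with_supcon)
    probs[b, ] <- caches[[b]]$head$probs
    ce <- ce - log(max(probs[b, yidx[b]], 1e-12))
  }
  ce <- ce / B
  sc <- list(loss = 0, grad = NULL)
  if (with_supcon && B >= 2L) {
    Z <- do.call(rbind, lapply(caches, function(cc) cc$proj$z))
    sc <- supcon_loss_grad(Z, yidx, tconf$temperature)
  }
  out <- list(ce = ce, supcon = sc$loss, probs = probs)
  if (!want_grad) return(out)
  grad <- numeric(length(params$theta))
  for (b in seq_len(B)) {
    dlogits <- caches[[b]]$head$probs
    dlogits[yidx[b]] <- dlogits[yidx[b]] - 1
    dlogits <- dlogits / B
    dz <- if (!is.null(sc$grad)) tconf$lambda_supcon * sc$grad[b, ] else NULL
    bw <- gnn_backward(caches[[b]], pl, params$schema, dlogits, dz = dz)
    grad <- grad + bw$grad
  }
  out$grad <- grad
  out
}

# eval-mode class probabilities for a list of graphs
predict_probs <- function(params, graphs, masks = NULL,
                          backend = c("compiled", "reference")) {
  backend <- match.arg(backend)
  config <- params$config
  Xs <- lapply(graphs, `[[`, "node_features")
  Ws <- lapply(graphs, `[[`, "weights")
  if (is.null(masks)) {
    masks <- lapply(graphs, function(g) default_masks(g$weights, config))
  }
  if (backend == "compiled") {
    probs <- cpp_forward_probs(
      Xs, Ws, masks, params$theta,
      as.integer(config_dims(config)) |> setNames(names(config_dims(config))),
      config$renormalize_attention
    )
  } else {
    pl <- unpack_params(params)
    probs <- t(vapply(seq_along(graphs), function(b) {
      gnn_forward_cache(Xs[[b]], Ws[[b]], masks[[b]], pl, config,
                        train = FALSE)$head$probs
    }, numeric(config$n_classes)))
  }
  colnames(probs) <- PDS_CLASSES[seq_len(config$n_classes)]
  probs
}
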