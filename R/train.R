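# Optimizer loop: Adam + warmup/cosine schedule + gradient clipping +
# stratified batches + early stopping on validation loss.

# split shuffled class indices into nb near-equal chunks, one per batch,
# so every batch keeps the cohort's class proportions
stratified_batches <- function(labels, batch_size) {
  N <- length(labels)
  nb <- max(1L, ceiling(N / batch_size))
  chunks <- vector("list", nb)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    grp <- sort(rep_len(seq_len(nb), length(idx)))
    for (b in seq_len(nb)) {
      chunks[[b]] <- c(chunks[[b]], idx[grp == b])
    }
  }
  lapply(chunks, sample)
}

#' Train the graph-transformer classifier
#'
#' Optimizes the composite objective (cross-entropy + L2 penalty +
#' weighted supervised-contrastive term) with Adam
#' (beta1 0.9, beta2 0.999, eps 1e-8), linear-warmup/cosine-decay
#' learning rate, global gradient-norm clipping, stratified mini-batches
#' and the four-part stochastic regularization suite.  A stratified
#' fraction of the cohort is held out to monitor validation loss
#' (cross-entropy plus the L2 penalty; the contrastive term is a
#' training-only device); early stopping restores the best weights.
#' Fully reproducible from the two seeds (model init and training).
#'
#' @param graphs list of labelled [metabolic_graph()].
#' @param config a [model_config()].
#' @param tconf a [train_config()].
#' @param init optional `gnn_params` to continue from (used by the
#'   pretrain/fine-tune protocol); fresh initialization when `NULL`.
#' @param backend `"compiled"` (default) or `"reference"`.
#' @param verbose print one line per epoch.
#' @param stop_at_train_acc optional convergence short-circuit: stop as
#'   soon as the model's accuracy on its own training set (eval mode,
#'   dropout off) reaches this threshold; used by capacity checks that
#'   only ask when the model first fits its training set.  When set, the
#'   history gains a `train_acc_eval` column.
#' @return A `pds_gnn_fit`: trained `params`, per-epoch `history`
#'   tibble, `best_epoch`, `best_val_loss` and bookkeeping.
#' @export
train_gnn <- function(graphs, config = model_config(),
                      tconf = train_config(), init = NULL,
                      backend = c("compiled", "reference"),
                      verbose = FALSE, stop_at_train_acc = NULL) {
  backend <- match.arg(backend)
  labels <- vapply(graphs, function(g) {
    if (is.null(g$label)) abort("all training graphs must be labelled")
    g$label
  }, character(1))
  assert_classes(labels)
  if (length(unique(labels)) < 2L) abort("need at least 2 classes to train")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(tconf$seed)

  # stratified validation split
  N <- length(graphs)
  val_idx <- integer(0)
  if (tconf$val_fraction > 0) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_val <- max(1L, round(length(idx) * tconf$val_fraction))
      if (n_val >= length(idx)) {
        abort(sprintf("validation split would leave class %s empty", cl))
      }
      val_idx <- c(val_idx, sample(idx, n_val))
    }
  }
  tr_idx <- setdiff(seq_len(N), val_idx)
  tr_labels <- labels[tr_idx]
  yidx_all <- match(labels, PDS_CLASSES)

  params <- init %||% init_params(config)
  if (length(params$theta) != length(init_params(config)$theta)) {
    abort("init params do not match the model config")
  }
  masks <- lapply(graphs, function(g) default_masks(g$weights, config))
  Xs <- lapply(graphs, `[[`, "node_features")
  Ws <- lapply(graphs, `[[`, "weights")

  # Adam state
  m <- numeric(length(params$theta))
  v <- numeric(length(params$theta))
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8

  best_theta <- params$theta
  best_val <- Inf
  best_epoch <- 0L
  stall <- 0L
  history <- vector("list", tconf$max_epochs)
  with_supcon <- tconf$lambda_supcon > 0

  val_loss_fn <- function() {
    if (length(val_idx) == 0L) return(c(loss = NA_real_, acc = NA_real_))
    pv <- predict_probs(params, graphs[val_idx],
                        masks = masks[val_idx], backend = backend)
    yt <- yidx_all[val_idx]
    ce <- mean(-log(pmax(pv[cbind(seq_along(yt), yt)], 1e-12)))
    c(loss = ce + tconf$lambda_l2 * sum(params$theta^2),
      acc = mean(max.col(pv) == yt))
  }

  for (epoch in seq_len(tconf$max_epochs)) {
    batches <- stratified_batches(tr_labels, tconf$batch_size)
    nb <- length(batches)
    ep_ce <- ep_sc <- ep_total <- 0
    ep_acc_n <- ep_acc_hit <- 0
    gnorm_post <- 0
    for (bi in seq_len(nb)) {
      bidx <- tr_idx[batches[[bi]]]
      lr <- lr_at_step(epoch - 1 + (bi - 1) / nb, tconf)
      pert <- apply_regularization(graphs[bidx], tconf, "train")
      res <- batch_grad(params,
                        lapply(pert, `[[`, "node_features"),
                        lapply(pert, `[[`, "weights"),
                        masks[bidx], yidx_all[bidx], tconf,
                        train = TRUE, want_grad = TRUE,
                        with_supcon = with_supcon, backend = backend)
      grad <- res$grad + 2 * tconf$lambda_l2 * params$theta
      gn <- sqrt(sum(grad^2))
      if (gn > tconf$clip_norm) grad <- grad * (tconf$clip_norm / gn)
      gnorm_post <- max(gnorm_post, min(gn, tconf$clip_norm))
      step <- step + 1L
      m <- b1 * m + (1 - b1) * grad
      v <- b2 * v + (1 - b2) * grad^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      params$theta <- params$theta - lr * mhat / (sqrt(vhat) + aeps)

      l2 <- tconf$lambda_l2 * sum(params$theta^2)
      ep_ce <- ep_ce + res$ce
      ep_sc <- ep_sc + res$supcon
      ep_total <- ep_total + res$ce + l2 + tconf$lambda_supcon * res$supcon
      ep_acc_hit <- ep_acc_hit + sum(max.col(res$probs) == yidx_all[bidx])
      ep_acc_n <- ep_acc_n + length(bidx)
    }
    vl <- val_loss_fn()
    improved <- is.finite(vl[["loss"]]) && vl[["loss"]] < best_val - 1e-9
    if (improved) {
      best_val <- vl[["loss"]]
      best_theta <- params$theta
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr_at_step(epoch - 1, tconf),
      train_loss = ep_total / nb, train_ce = ep_ce / nb,
      train_supcon = ep_sc / nb, train_acc = ep_acc_hit / ep_acc_n,
      val_loss = vl[["loss"]], val_acc = vl[["acc"]],
      grad_norm = gnorm_post, best = improved
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d lr %.2e train %.4f acc %.3f val %.4f acc %.3f%s",
        epoch, history[[epoch]]$lr, ep_total / nb, ep_acc_hit / ep_acc_n,
        vl[["loss"]], vl[["acc"]], if (improved) " *" else ""))
    }
    if (!is.null(stop_at_train_acc)) {
      ptr <- predict_probs(params, graphs[tr_idx], masks = masks[tr_idx],
                           backend = backend)
      acc_eval <- mean(max.col(ptr) == yidx_all[tr_idx])
      history[[epoch]]$train_acc_eval <- acc_eval
      if (acc_eval >= stop_at_train_acc) break
    }
    if (length(val_idx) > 0L && stall >= tconf$patience) break
  }
  if (length(val_idx) > 0L) params$theta <- best_theta
  structure(
    list(params = params, config = config, tconf = tconf,
         history = dplyr::bind_rows(history),
         best_epoch = if (length(val_idx)) best_epoch else epoch,
         best_val_loss = if (length(val_idx)) best_val else NA_real_,
         n_train = length(tr_idx), n_val = length(val_idx),
         backend = backend),
    class = "pds_gnn_fit"
  )
}

#' @export
print.pds_gnn_fit <- function(x, ...) {
  cat(sprintf(paste0("<pds_gnn_fit> %d epochs (best %d), %d train / %d val",
                     " subjects, val loss %.4f\n"),
              nrow(x$history), x$best_epoch, x$n_train, x$n_val,
              x$best_val_loss))
  invisible(x)
}

#' Two-stage pretrain / fine-tune protocol
#'
#' Stage 1 trains from scratch on the pretraining cohort (clinically
#' possible diagnoses, in the published setting); stage 2 continues from
#' the stage-1 best weights on the fine-tuning cohort with a fresh
#' learning-rate schedule.  An empty pretraining cohort reduces to plain
#' training on the fine-tuning cohort.
#'
#' @param pretrain_graphs list of labelled graphs (may be empty).
#' @param finetune_graphs list of labelled graphs.
#' @param config a [model_config()].
#' @param pre_tconf,fine_tconf [train_config()] for each stage.
#' @param backend computation backend.
#' @param verbose print per-epoch lines.
#' @return A `pds_gnn_fit` for the fine-tuned model, with the stage-1
#'   fit attached as `$pretrain_fit` (`NULL` if stage 1 was skipped).
#' @export
pretrain_finetune <- function(pretrain_graphs, finetune_graphs,
                              config = model_config(),
                              pre_tconf = train_config(),
                              fine_tconf = pre_tconf,
                              backend = c("compiled", "reference"),
                              verbose = FALSE) {
  backend <- match.arg(backend)
  if (length(pretrain_graphs) == 0L) {
    return(train_gnn(finetune_graphs, config, fine_tconf,
                     backend = backend, verbose = verbose))
  }
  stage1 <- train_gnn(pretrain_graphs, config, pre_tconf,
                      backend = backend, verbose = verbose)
  fit <- train_gnn(finetune_graphs, config, fine_tconf,
                   init = stage1$params, backend = backend,
                   verbose = verbose)
  fit$pretrain_fit <- stage1
  fit
}

#' Predict diagnosis classes for graphs
#'
#' @param object a `pds_gnn_fit`.
#' @param graphs list of [metabolic_graph()].
#' @param ... unused.
#' @return A tibble with `subject_id`, the true `label` where present,
#'   the predicted class `.pred_class` and one probability column per
#'   class.
#' @export
predict.pds_gnn_fit <- function(object, graphs, ...) {
  probs <- predict_probs(object$params, graphs, backend = object$backend)
  tibble::tibble(
    subject_id = vapply(graphs, `[[`, character(1), "subject_id"),
    label = vapply(graphs, function(g) g$label %||% NA_character_,
                   character(1)),
    .pred_class = PDS_CLASSES[max.col(probs)],
    .pred_IPD = probs[, "IPD"], .pred_MSA = probs[, "MSA"],
    .pred_PSP = probs[, "PSP"]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fit
#'
#' @param x a `pds_gnn_fit`.
#' @param ... unused.
#' @return The history tibble (one row per epoch).
#' @export
tidy.pds_gnn_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x a `pds_gnn_fit`.
#' @param ... unused.
#' @return A one-row tibble: epochs run, best epoch, best validation
#'   loss, final training accuracy, parameter count.
#' @export
glance.pds_gnn_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history), best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    train_acc = utils::tail(x$history$train_acc, 1),
    n_parameters = length(x$params$theta),
    n_train = x$n_train, n_val = x$n_val
  )
}
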