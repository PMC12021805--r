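#' Training protocol configuration
#'
#' Defaults follow the published protocol: composite loss
#' `CE + 1e-4 ||theta||^2 + 0.2 L_SupCon` at temperature 0.07, Adam with
#' linear warmup from 0 to 5e-4 over 5 epochs then cosine decay to 1e-6,
#' global gradient-norm clipping at 3.0, at most 200 epochs with batch
#' size 32, stratified batches, early stopping on validation loss with
#' patience 10 (best weights restored), and a four-part regularization
#' suite (15% node-feature dropout, 0.1 attention dropout, 0.4 dropout in
#' the fully connected head, Gaussian noise on 10% of edges).
#'
#' @param lambda_l2 L2 penalty weight.
#' @param lambda_supcon supervised-contrastive loss weight.
#' @param temperature SupCon temperature.
#' @param lr_peak,lr_floor peak and final learning rates.
#' @param warmup_epochs linear warmup length (epochs).
#' @param max_epochs maximum training epochs.
#' @param batch_size mini-batch size.
#' @param clip_norm global gradient-norm clip.
#' @param patience early-stopping patience (epochs).
#' @param node_feature_dropout probability of zeroing a node's feature row.
#' @param edge_noise_fraction fraction of off-diagonal edges perturbed.
#' @param edge_noise_sigma standard deviation of the edge noise, on the
#'   `[0, 1]` weight scale.
#' @param val_fraction stratified fraction of the cohort held out for
#'   validation-loss monitoring.
#' @param seed training seed (shuffling, dropout, splits).
#' @return A `train_config` list.
#' @export
train_config <- function(lambda_l2 = 1e-4, lambda_supcon = 0.2,
                         temperature = 0.07, lr_peak = 5e-4,
                         lr_floor = 1e-6, warmup_epochs = 5L,
                         max_epochs = 200L, batch_size = 32L,
                         clip_norm = 3.0, patience = 10L,
                         node_feature_dropout = 0.15,
                         edge_noise_fraction = 0.10,
                         edge_noise_sigma = 0.05,
                         val_fraction = 0.15, seed = 1L) {
  rates <- c(node_feature_dropout, edge_noise_fraction, val_fraction)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (lr_floor >= lr_peak) abort("lr_floor must be below lr_peak")
  if (patience >= max_epochs) abort("patience must be below max_epochs")
  structure(
    list(lambda_l2 = lambda_l2, lambda_supcon = lambda_supcon,
         temperature = temperature, lr_peak = lr_peak, lr_floor = lr_floor,
         warmup_epochs = as.integer(warmup_epochs),
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size), clip_norm = clip_norm,
         patience = as.integer(patience),
         node_feature_dropout = node_feature_dropout,
         edge_noise_fraction = edge_noise_fraction,
         edge_noise_sigma = edge_noise_sigma,
         val_fraction = val_fraction, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning rate at a (possibly fractional) epoch
#'
#' Linear warmup from 0 to `lr_peak` over `warmup_epochs`, then cosine
#' decay to `lr_floor` at `max_epochs`:
#' `lr = floor + (peak - floor) * (1 + cos(pi (e - w) / (E - w))) / 2`.
#'
#' @param epoch real-valued epoch in `[0, max_epochs]`.
#' @param config a [train_config()].
#' @return The learning rate.
#' @export
lr_at_step <- function(epoch, config) {
  w <- config$warmup_epochs; E <- config$max_epochs
  ifelse(epoch < w,
         config$lr_peak * epoch / w,
         config$lr_floor + (config$lr_peak - config$lr_floor) *
           (1 + cos(pi * (epoch - w) / (E - w))) / 2)
}

#' Supervised contrastive loss
#'
#' Canonical supervised-contrastive form on unit-norm embeddings: for
#' each anchor `i` with positive set `P(i)` (same-label, non-anchor),
#' `-(1/|P(i)|) sum_p log[exp(z_i.z_p / tau) / sum_{a != i} exp(z_i.z_a / tau)]`,
#' averaged over anchors with a non-empty positive set.  Anchors without
#' positives are skipped; if no anchor has positives the loss is 0 with
#' a warning.
#'
#' @param z matrix of unit-norm embeddings, one row per sample.
#' @param labels class labels, one per row.
#' @param temperature temperature tau (default 0.07).
#' @return The scalar loss.
#' @export
supcon_loss <- function(z, labels, temperature = 0.07) {
  supcon_loss_grad(z, labels, temperature, want_grad = FALSE)$loss
}

# loss plus gradient with respect to z (rows)
supcon_loss_grad <- function(z, labels, temperature = 0.07,
                             want_grad = TRUE) {
  z <- as.matrix(z)
  B <- nrow(z)
  stopifnot(length(labels) == B)
  if (B < 2L) return(list(loss = 0, grad = matrix(0, B, ncol(z))))
  S <- tcrossprod(z) / temperature
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  npos <- rowSums(same)
  anchors <- which(npos > 0)
  if (length(anchors) == 0L) {
    warn("no anchor has a positive pair; SupCon loss is 0")
    return(list(loss = 0, grad = matrix(0, B, ncol(z))))
  }
  # log-sum-exp over non-anchor entries, per row
  E <- exp(S)
  diag(E) <- 0
  lse <- log(rowSums(E))
  loss <- 0
  G <- matrix(0, B, B) # d loss / d S
  for (i in anchors) {
    pos <- which(same[i, ])
    loss <- loss - sum(S[i, pos] - lse[i]) / npos[i]
    if (want_grad) {
      q <- E[i, ] / sum(E[i, ])
      G[i, ] <- G[i, ] + q - (same[i, ] / npos[i])
    }
  }
  loss <- loss / length(anchors)
  if (!want_grad) return(list(loss = loss))
  G <- G / length(anchors)
  grad <- (G %*% z + crossprod(G, z)) / temperature
  list(loss = loss, grad = grad)
}

#' Composite training loss breakdown
#'
#' `L = CE + lambda_l2 ||theta||^2 + lambda_supcon L_SupCon`, with the
#' cross-entropy averaged over the batch using true one-hot labels
#' (probabilities clamped at 1e-12 before the log), the L2 penalty over
#' every learnable parameter, and the supervised contrastive term over
#' the batch's unit-norm projection embeddings.
#'
#' @param probs matrix of predicted class probabilities, one row per
#'   subject (columns in `IPD`, `MSA`, `PSP` order).
#' @param labels true class labels.
#' @param params a `gnn_params` (for the L2 term); `NULL` drops it.
#' @param embeddings unit-norm embedding matrix for SupCon; `NULL` drops
#'   the term.
#' @param config a [train_config()].
#' @return A `loss_breakdown`: `total`, `cross_entropy`, `l2_penalty`,
#'   `supcon`.
#' @export
composite_loss <- function(probs, labels, params = NULL, embeddings = NULL,
                           config = train_config()) {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == length(labels))
  y_idx <- match(labels, PDS_CLASSES[seq_len(ncol(probs))])
  if (anyNA(y_idx)) abort("labels outside the class set")
  p_true <- pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-12)
  ce <- mean(-log(p_true))
  l2 <- if (is.null(params)) 0 else config$lambda_l2 * sum(params$theta^2)
  sc <- if (is.null(embeddings)) 0 else {
    supcon_loss(embeddings, labels, config$temperature)
  }
  structure(list(total = ce + l2 + config$lambda_supcon * sc,
                 cross_entropy = ce, l2_penalty = l2, supcon = sc),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss> total %.6f = CE %.6f + L2 %.6f + supcon %.6f (weighted)\n",
              x$total, x$cross_entropy, x$l2_penalty,
              x$total - x$cross_entropy - x$l2_penalty))
  invisible(x)
}
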