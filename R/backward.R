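# Analytic backward pass mirroring gnn_forward_cache().  Gradients are
# accumulated into an environment keyed by schema name and flattened to
# the schema order at the end.  Verified against central finite
# differences in the test suite.

grad_env_new <- function(schema) {
  e <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(schema))) {
    assign(schema$name[i], numeric(schema$size[i]), envir = e)
  }
  e
}

grad_add <- function(e, name, value) {
  assign(name, get(name, envir = e) + as.numeric(value), envir = e)
}

grad_flatten <- function(e, schema) {
  unlist(lapply(schema$name, function(n) get(n, envir = e)),
         use.names = FALSE)
}

# backward through a row-wise LayerNorm; returns dR and accumulates
# scale/offset grads
layer_norm_rows_bwd <- function(dY, ln, g) {
  n <- nrow(dY)
  dXhat <- dY * rep(g, each = n)
  dg <- colSums(dY * ln$Xhat)
  db <- colSums(dY)
  dR <- ln$inv * (dXhat - rowMeans(dXhat) - ln$Xhat * rowMeans(dXhat * ln$Xhat))
  list(dR = dR, dg = dg, db = db)
}

layer_norm_vec_bwd <- function(dy, ln, g) {
  dxhat <- dy * g
  list(dx = ln$inv * (dxhat - mean(dxhat) - ln$xhat * mean(dxhat * ln$xhat)),
       dg = dy * ln$xhat, db = dy)
}

# backward through one transformer layer; dXout is the gradient at the
# layer output; returns gradient at the layer input
layer_backward <- function(dXout, L, lp, lname, ge, config) {
  n <- nrow(dXout); d <- config$d_model
  p <- function(x) sprintf("%s.%s", lname, x)
  lnb <- layer_norm_rows_bwd(dXout, L$ln, lp$lng)
  grad_add(ge, p("lng"), lnb$dg)
  grad_add(ge, p("lnb"), lnb$db)
  dR <- lnb$dR
  dXin <- dR

  # FFN branch
  dFf <- dR
  grad_add(ge, p("b2"), colSums(dFf))
  grad_add(ge, p("W2"), crossprod(dFf, L$Hg))
  dHg <- dFf %*% lp$W2
  dH1 <- dHg * gelu_grad(L$H1)
  grad_add(ge, p("b1"), colSums(dH1))
  grad_add(ge, p("W1"), crossprod(dH1, L$Xf))
  dXf <- dH1 %*% lp$W1

  # attention branch
  dXatt <- dR
  grad_add(ge, p("Wo"), crossprod(L$att$Ocat, dXatt))
  dOcat <- tcrossprod(dXatt, lp$Wo)
  dv <- config$d_v
  p_att <- if (isTRUE(L$train_dropout)) config$attention_dropout else 0
  for (h in seq_len(config$n_heads)) {
    hd <- L$att$heads[[h]]
    dO <- dOcat[, (h - 1L) * dv + seq_len(dv), drop = FALSE]
    dAt <- tcrossprod(dO, hd$V)
    dV <- crossprod(hd$At, dO)
    if (!is.null(hd$rs)) {
      # renormalized rows: At = T / rs with T = Ad * Wedge
      Tm <- hd$At * hd$rs
      dT <- dAt / hd$rs - rowSums(dAt * Tm) / hd$rs^2
      dAd <- dT * L$WedgeRef
    } else {
      dAd <- dAt * L$WedgeRef
    }
    dA <- if (!is.null(hd$D)) dAd * hd$D else dAd
    dSc <- hd$A * (dA - rowSums(dA * hd$A))
    sc <- 1 / sqrt(config$d_k)
    dQ <- (dSc %*% hd$K) * sc
    dK <- crossprod(dSc, hd$Q) * sc
    grad_add(ge, p(sprintf("Wq%d", h)), crossprod(L$Xf, dQ))
    grad_add(ge, p(sprintf("Wk%d", h)), crossprod(L$Xf, dK))
    grad_add(ge, p(sprintf("Wv%d", h)), crossprod(L$Xf, dV))
    dXf <- dXf + tcrossprod(dQ, lp$Wq[[h]]) + tcrossprod(dK, lp$Wk[[h]]) +
      tcrossprod(dV, lp$Wv[[h]])
  }

  # gated fusion
  dG <- dXf * (L$Xin - L$Smat)
  dXin <- dXin + dXf * L$G
  ds <- colSums(dXf * (1 - L$G))
  dU <- dG * L$G * (1 - L$G)
  grad_add(ge, p("Wg"), crossprod(L$Cc, dU))
  dCc <- tcrossprod(dU, lp$Wg)
  dXin <- dXin + dCc[, seq_len(d), drop = FALSE]
  ds <- ds + colSums(dCc[, d + seq_len(d), drop = FALSE])
  grad_add(ge, p("s"), ds)
  dXin
}

head_backward <- function(dlogits, hf, hp, ge) {
  grad_add(ge, "head.Wc", outer(dlogits, hf$d2))
  grad_add(ge, "head.bc", dlogits)
  dd2 <- as.vector(crossprod(hp$Wc, dlogits))
  du2 <- dd2 * hf$m2
  l2 <- layer_norm_vec_bwd(du2, hf$ln2, hp$ln2g)
  grad_add(ge, "head.ln2g", l2$dg); grad_add(ge, "head.ln2b", l2$db)
  db_pre <- l2$dx * gelu_grad(hf$b_pre)
  grad_add(ge, "head.Wb", outer(db_pre, hf$d1))
  grad_add(ge, "head.bb", db_pre)
  dd1 <- as.vector(crossprod(hp$Wb, db_pre))
  du1 <- dd1 * hf$m1
  l1 <- layer_norm_vec_bwd(du1, hf$ln1, hp$ln1g)
  grad_add(ge, "head.ln1g", l1$dg); grad_add(ge, "head.ln1b", l1$db)
  da_pre <- l1$dx * gelu_grad(hf$a_pre)
  grad_add(ge, "head.Wa", outer(da_pre, hf$d0))
  grad_add(ge, "head.ba", da_pre)
  dd0 <- as.vector(crossprod(hp$Wa, da_pre))
  du0 <- dd0 * hf$m0
  l0 <- layer_norm_vec_bwd(du0, hf$ln0, hp$ln0g)
  grad_add(ge, "head.ln0g", l0$dg); grad_add(ge, "head.ln0b", l0$db)
  l0$dx
}

proj_backward <- function(dz, pf, pp, hcat, ge) {
  # through the L2 normalization z = q / ||q||
  dq <- (dz - pf$z * sum(pf$z * dz)) / pf$nrm
  grad_add(ge, "proj.W2", outer(dq, pf$p_act))
  grad_add(ge, "proj.b2", dq)
  dp_act <- as.vector(crossprod(pp$W2, dq))
  dp_pre <- dp_act * gelu_grad(pf$p_pre)
  grad_add(ge, "proj.W1", outer(dp_pre, hcat))
  grad_add(ge, "proj.b1", dp_pre)
  as.vector(crossprod(pp$W1, dp_pre))
}

# full backward for one graph: dlogits (length C) and optionally dz
# (gradient at the normalized SupCon embedding).  Returns the flat
# parameter gradient plus the gradient at the input node features.
gnn_backward <- function(fw, pl, schema, dlogits, dz = NULL) {
  config <- fw$config
  ge <- grad_env_new(schema)
  dhcat <- head_backward(dlogits, fw$head, pl$head, ge)
  if (!is.null(dz)) {
    dhcat <- dhcat + proj_backward(dz, fw$proj, pl$proj, fw$hcat, ge)
  }
  d <- config$d_model
  nl <- config$n_layers
  dXout <- vector("list", nl)
  for (l in seq_len(nl)) {
    dXl <- matrix(0, config$n_nodes, d)
    dh <- dhcat[(l - 1L) * d + seq_len(d)]
    dXl[cbind(fw$pool_idx[[l]], seq_len(d))] <- dh
    dXout[[l]] <- dXl
  }
  dX <- matrix(0, config$n_nodes, d)
  for (l in rev(seq_len(nl))) {
    L <- fw$layers[[l]]
    L$train_dropout <- fw$train
    L$WedgeRef <- fw$Wedge
    dX <- layer_backward(dXout[[l]] + dX, L, pl$layers[[l]],
                         sprintf("L%d", l), ge, config)
  }
  list(grad = grad_flatten(ge, schema), dX0 = dX)
}
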