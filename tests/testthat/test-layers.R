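test_that("topk_sparsify matches a sort-based oracle and is symmetric", {
  set.seed(30)
  n <- 12
  W <- rand_weights(n)
  k <- 4
  mask <- topk_sparsify(W, k)
  # oracle: per-row top-k by weight, lower index on ties, then union
  oracle <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    ord <- order(-w, seq_len(n))
    oracle[i, ord[seq_len(k)]] <- TRUE
  }
  oracle <- oracle | t(oracle)
  diag(oracle) <- TRUE
  expect_identical(mask, oracle)
  expect_identical(mask, t(mask))
  expect_true(all(diag(mask)))
})

test_that("topk saturates at k >= n - 1 and ties break to lower index", {
  W <- rand_weights(8)
  expect_true(all(topk_sparsify(W, 7)))
  expect_warning(m <- topk_sparsify(W, 8), "full graph")
  expect_true(all(m))

  # star graph: node 1 dominates every row; k = 1 keeps only the star
  n <- 6
  W <- matrix(0.2, n, n)
  W[1, ] <- W[, 1] <- 0.9
  diag(W) <- 1
  m <- topk_sparsify(W, 1)
  expected <- diag(n) == 1
  expected[1, ] <- expected[, 1] <- TRUE
  expect_identical(m, expected)

  # exact ties: all equal weights, k = 2 keeps the two lowest indices
  W <- matrix(0.5, 5, 5); diag(W) <- 1
  m <- topk_sparsify(W, 2)
  expect_identical(which(m[4, ]), c(1L, 2L, 4L)) # {1,2} by tie rule + diagonal
  expect_identical(which(m[1, ]), c(1L, 2L, 3L, 4L, 5L)) # union with others' picks
})

test_that("gated fusion follows its closed form", {
  set.seed(31)
  n <- 7; d <- 5
  X <- matrix(rnorm(n * d), n, d)
  s <- rnorm(d)
  Wg <- matrix(rnorm(2 * d * d, 0, 0.3), 2 * d, d)

  # W_g = 0: gate is exactly 1/2 everywhere
  half <- gated_structure_fusion(X, s, matrix(0, 2 * d, d))
  expect_equal(half, (X + matrix(s, n, d, byrow = TRUE)) / 2,
               tolerance = 1e-15)

  # s equal to a row of X: that row is a fixed point for any gate
  Xs <- X; Xs[3, ] <- s
  fused <- gated_structure_fusion(Xs, s, Wg)
  expect_equal(fused[3, ], s, tolerance = 1e-15)

  # element-wise oracle
  out <- gated_structure_fusion(X, s, Wg)
  for (i in seq_len(n)) {
    g <- 1 / (1 + exp(-as.vector(c(X[i, ], s) %*% Wg)))
    expect_equal(out[i, ], g * X[i, ] + (1 - g) * s, tolerance = 1e-12)
  }
})

test_that("feed-forward network follows W2 GELU(W1 x + b1) + b2", {
  set.seed(32)
  n <- 6; d <- 4; h <- 9
  W1 <- matrix(rnorm(h * d), h, d); b1 <- rnorm(h)
  W2 <- matrix(rnorm(d * h), d, h); b2 <- rnorm(d)

  # x = 0, b1 = 0: GELU(0) = 0 so the output is exactly b2
  out0 <- feed_forward(matrix(0, n, d), W1, rep(0, h), W2, b2)
  expect_equal(out0, matrix(b2, n, d, byrow = TRUE), tolerance = 1e-15)

  # large positive pre-activations: GELU ~ identity
  Xbig <- matrix(5, n, d)
  expect_equal(feed_forward(Xbig, abs(W1), b1 + 10, W2, b2),
               t(W2 %*% (abs(W1) %*% t(Xbig) + b1 + 10) + b2),
               tolerance = 1e-6)

  # scalar-loop oracle with the exact Gaussian-CDF GELU
  X <- matrix(rnorm(n * d), n, d)
  out <- feed_forward(X, W1, b1, W2, b2)
  for (i in seq_len(n)) {
    pre <- as.vector(W1 %*% X[i, ]) + b1
    act <- vapply(pre, function(z) z * pnorm(z), 0)
    expect_equal(out[i, ], as.vector(W2 %*% act) + b2, tolerance = 1e-10)
  }
})

test_that("masked attention matches a dense loop-based oracle", {
  set.seed(33)
  cfg <- toy_config(n_nodes = 6)
  params <- init_params(cfg)
  X <- matrix(rnorm(6 * cfg$d_model), 6)
  W <- rand_weights(6)
  mask <- topk_sparsify(W, 3)
  res <- graph_attention(X, W, params, layer = 1, mask = mask)

  dk <- cfg$d_k
  Ocat <- NULL
  for (h in seq_len(cfg$n_heads)) {
    Q <- X %*% par_get(params, sprintf("L1.Wq%d", h))
    K <- X %*% par_get(params, sprintf("L1.Wk%d", h))
    V <- X %*% par_get(params, sprintf("L1.Wv%d", h))
    A <- matrix(0, 6, 6)
    for (i in 1:6) {
      sc <- vapply(1:6, function(j) {
        if (!mask[i, j]) return(-Inf)
        sum(Q[i, ] * K[j, ]) / sqrt(dk)
      }, 0)
      e <- exp(sc - max(sc))
      A[i, ] <- e / sum(e)
    }
    expect_equal(res$attention[[h]], A, tolerance = 1e-10)
    O <- (A * W) %*% V # Hadamard then value aggregation
    Ocat <- cbind(Ocat, O)
  }
  expect_equal(res$output, Ocat %*% par_get(params, "L1.Wo"),
               tolerance = 1e-10)
  # pre-Hadamard rows are stochastic
  for (h in seq_len(cfg$n_heads)) {
    expect_equal(rowSums(res$attention[[h]]), rep(1, 6), tolerance = 1e-6)
  }
})

test_that("degenerate attention configurations behave as forced", {
  set.seed(34)
  cfg <- toy_config(n_nodes = 5)
  params <- init_params(cfg)
  n <- 5
  X <- matrix(rnorm(n * cfg$d_model), n)

  # zero query/key projections: uniform attention; all-ones weights keep it
  for (h in seq_len(cfg$n_heads)) {
    params <- par_set(params, sprintf("L1.Wq%d", h),
                      matrix(0, cfg$d_model, cfg$d_k))
    params <- par_set(params, sprintf("L1.Wk%d", h),
                      matrix(0, cfg$d_model, cfg$d_k))
  }
  ones <- matrix(1, n, n)
  res <- graph_attention(X, ones, params, layer = 1)
  Vbar <- NULL
  for (h in seq_len(cfg$n_heads)) {
    expect_equal(res$attention[[h]], matrix(1 / n, n, n), tolerance = 1e-12)
    V <- X %*% par_get(params, sprintf("L1.Wv%d", h))
    Vbar <- cbind(Vbar, matrix(colMeans(V), n, cfg$d_v, byrow = TRUE))
  }
  expect_equal(res$output, Vbar %*% par_get(params, "L1.Wo"),
               tolerance = 1e-10)

  # identity connectivity: the Hadamard annihilates off-diagonal messages
  params2 <- init_params(cfg)
  idw <- diag(n)
  res2 <- graph_attention(X, idw, params2, layer = 1)
  Oid <- NULL
  for (h in seq_len(cfg$n_heads)) {
    A <- res2$attention[[h]]
    V <- X %*% par_get(params2, sprintf("L1.Wv%d", h))
    Oid <- cbind(Oid, diag(A) * V) # only the self term survives
  }
  expect_equal(res2$output, Oid %*% par_get(params2, "L1.Wo"),
               tolerance = 1e-10)

  expect_error(graph_attention(X * NA, idw, params2, 1), "non-finite")
})

test_that("a transformer layer composes fusion, attention, FFN and LayerNorm", {
  set.seed(35)
  cfg <- toy_config(n_nodes = 6)
  params <- init_params(cfg)
  n <- 6
  X <- matrix(rnorm(n * cfg$d_model), n)
  W <- rand_weights(n)
  g <- metabolic_graph(matrix(runif(n * cfg$d_model), n), W)
  mask <- topk_sparsify(W, cfg$topk_neighbors)

  out <- transformer_layer(X, g, params, layer = 2, mask = mask)

  # step-by-step oracle from the exported building blocks
  Xf <- gated_structure_fusion(X, par_get(params, "L2.s"),
                               par_get(params, "L2.Wg"))
  att <- graph_attention(Xf, W, params, layer = 2, mask = mask)
  ffn <- feed_forward(Xf, par_get(params, "L2.W1"), par_get(params, "L2.b1"),
                      par_get(params, "L2.W2"), par_get(params, "L2.b2"))
  R <- X + att$output + ffn
  lng <- par_get(params, "L2.lng"); lnb <- par_get(params, "L2.lnb")
  oracle <- t(apply(R, 1, function(r) {
    xhat <- (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)
    lng * xhat + lnb
  }))
  expect_equal(out, oracle, tolerance = 1e-8)

  # LayerNorm rows are standardized before scale/offset
  xhat <- (R - rowMeans(R)) / sqrt(rowMeans((R - rowMeans(R))^2) + 1e-5)
  expect_equal(rowMeans(xhat), rep(0, n), tolerance = 1e-12)
  expect_equal(rowMeans(xhat^2), rep(1, n), tolerance = 1e-4)

  # zeroed attention and FFN weights leave LayerNorm(X + constants)
  pz <- params
  for (h in seq_len(cfg$n_heads)) {
    pz <- par_set(pz, sprintf("L2.Wv%d", h), matrix(0, cfg$d_model, cfg$d_v))
  }
  pz <- par_set(pz, "L2.W2", matrix(0, cfg$d_model, cfg$d_ffn))
  outz <- transformer_layer(X, g, pz, layer = 2, mask = mask)
  Rz <- X + matrix(par_get(pz, "L2.b2"), n, cfg$d_model, byrow = TRUE)
  oraclez <- t(apply(Rz, 1, function(r) {
    xhat <- (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)
    lng * xhat + lnb
  }))
  expect_equal(outz, oraclez, tolerance = 1e-8)
})
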