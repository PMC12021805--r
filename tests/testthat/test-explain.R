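test_that("edge importance is the layer mean of head-averaged attention", {
  set.seed(100)
  n <- 6
  mk <- function() matrix(runif(n * n), n)
  # identical maps across layers: the mean is that map (symmetrized)
  M <- mk()
  tr1 <- structure(list(attention = list(list(M), list(M), list(M))),
                   class = "forward_trace")
  expect_equal(edge_importance(tr1), (M + t(M)) / 2, tolerance = 1e-12)

  # M, 0, 0 across layers: linearity gives M / 3
  zero <- matrix(0, n, n)
  tr2 <- structure(list(attention = list(list(M), list(zero), list(zero))),
                   class = "forward_trace")
  expect_equal(edge_importance(tr2), (M + t(M)) / 6, tolerance = 1e-12)

  # random multi-head maps against an explicit summation oracle
  maps <- lapply(1:3, function(l) lapply(1:4, function(h) mk()))
  tr3 <- structure(list(attention = maps), class = "forward_trace")
  acc <- matrix(0, n, n)
  for (l in 1:3) {
    hm <- matrix(0, n, n)
    for (h in 1:4) hm <- hm + maps[[l]][[h]]
    acc <- acc + hm / 4
  }
  acc <- acc / 3
  expect_equal(edge_importance(tr3), (acc + t(acc)) / 2, tolerance = 1e-12)
})

test_that("edge retention keeps the exact top fraction with stable ties", {
  set.seed(101)
  # 96-node graph: 15% of 4560 pairs = 684
  I <- rand_weights(96)
  kept <- retain_top_edges(I, 0.15)
  expect_identical(nrow(kept), as.integer(ceiling(0.15 * choose(96, 2))))
  expect_identical(nrow(kept), 684L)
  expect_identical(nrow(retain_top_edges(I, 1.0)), 4560L)
  # the kept scores dominate the dropped ones
  all_scores <- I[upper.tri(I)]
  thr <- min(I[kept])
  expect_lte(sum(all_scores > thr), nrow(kept))

  # uniform scores: lexicographic pair order decides
  U <- matrix(1, 10, 10)
  keptu <- retain_top_edges(U, 0.1) # ceiling(0.1 * 45) = 5
  expect_identical(keptu[, "i"], c(1L, 1L, 1L, 1L, 1L))
  expect_identical(keptu[, "j"], c(2L, 3L, 4L, 5L, 6L))

  # exact cardinality across random sizes and fractions
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    f <- runif(1, 0.01, 0.99)
    M <- rand_weights(n)
    expect_identical(nrow(retain_top_edges(M, f)),
                     as.integer(ceiling(f * n * (n - 1) / 2)))
  }
})

test_that("jaccard similarity behaves as a set overlap", {
  A <- rbind(c(1, 2), c(2, 3), c(3, 4))
  B <- rbind(c(2, 3), c(3, 4), c(4, 5))
  expect_equal(jaccard_similarity(A, B), 0.5) # 2 shared of 4 total
  expect_equal(jaccard_similarity(A, A), 1)
  expect_equal(jaccard_similarity(A, rbind(c(7, 8))), 0)
  expect_equal(jaccard_similarity(A[0, ], B[0, ]), 1) # empty sets agree
  # unordered pairs: orientation is irrelevant
  expect_equal(jaccard_similarity(A, A[, 2:1]), 1)
  # symmetric and bounded on random sets
  set.seed(102)
  for (i in 1:20) {
    X <- cbind(sample(10, 6, TRUE), sample(10, 6, TRUE))
    Y <- cbind(sample(10, 6, TRUE), sample(10, 6, TRUE))
    X <- X[X[, 1] != X[, 2], , drop = FALSE]
    Y <- Y[Y[, 1] != Y[, 2], , drop = FALSE]
    j1 <- jaccard_similarity(X, Y)
    expect_equal(j1, jaccard_similarity(Y, X))
    expect_gte(j1, 0); expect_lte(j1, 1)
  }
})

test_that("ROI mapping ranks regions with stable ties", {
  atlas <- default_atlas()
  one_hot <- rep(0, 96)
  one_hot[37] <- 1
  rep1 <- map_to_rois(one_hot, atlas)
  expect_identical(rep1$region[1], atlas$name[37])
  expect_identical(rep1$rank, 1:96)

  flat <- map_to_rois(rep(0.5, 96), atlas)
  expect_identical(flat$region, atlas$name) # stable atlas order on ties

  set.seed(103)
  sc <- runif(96)
  rep2 <- map_to_rois(sc, atlas)
  expect_identical(rep2$index, order(sc, decreasing = TRUE))
  expect_error(map_to_rois(rep(1, 50), atlas), "length")
})

test_that("node importance matches finite differences of log p(y|G)", {
  set.seed(104)
  cfg <- toy_config(n_nodes = 6, seed = 13)
  params <- init_params(cfg)
  n <- 6
  X <- matrix(runif(n * cfg$d_model), n)
  W <- rand_weights(n)
  g <- metabolic_graph(X, W)
  masks <- pdsgraph:::default_masks(W, cfg)
  pl <- pdsgraph:::unpack_params(params)
  fw <- pdsgraph:::gnn_forward_cache(X, W, masks, pl, cfg)
  y <- which.max(fw$head$probs)
  dlogits <- -fw$head$probs; dlogits[y] <- dlogits[y] + 1
  bw <- pdsgraph:::gnn_backward(fw, pl, params$schema, dlogits)
  imp <- sqrt(rowSums(bw$dX0^2))

  eps <- 1e-5
  fd <- matrix(0, n, cfg$d_model)
  for (i in seq_len(n)) {
    for (j in seq_len(cfg$d_model)) {
      lp <- function(Xm) {
        f <- pdsgraph:::gnn_forward_cache(Xm, W, masks, pl, cfg)
        log(max(f$head$probs[y], 1e-12))
      }
      Xp <- X; Xp[i, j] <- Xp[i, j] + eps
      Xm2 <- X; Xm2[i, j] <- Xm2[i, j] - eps
      fd[i, j] <- (lp(Xp) - lp(Xm2)) / (2 * eps)
    }
  }
  expect_equal(imp, sqrt(rowSums(fd^2)), tolerance = 1e-4)
  expect_true(all(imp >= 0))
})

test_that("a shadowed isolated zero node has exactly zero importance", {
  set.seed(105)
  # all layers masked; nodes 5 and 6 are isolated (self-edge only) with
  # identical zero feature rows.  Node 6 can never win a pooling maximum
  # (node 5 shadows it at a lower index) and no message leaves it, so no
  # gradient path reaches node 6.
  cfg <- toy_config(n_nodes = 6, seed = 14,
                    mask_layers = c(TRUE, TRUE))
  params <- init_params(cfg)
  X <- matrix(runif(6 * cfg$d_model), 6)
  X[5, ] <- 0
  X[6, ] <- 0
  W <- rand_weights(6)
  W[5, -5] <- 0; W[-5, 5] <- 0
  W[6, -6] <- 0; W[-6, 6] <- 0
  mask <- diag(6) == 1
  mask[1:4, 1:4] <- TRUE
  g <- metabolic_graph(X, W)
  pl <- pdsgraph:::unpack_params(params)
  masks <- list(mask, mask)
  fw <- pdsgraph:::gnn_forward_cache(X, W, masks, pl, cfg)
  y <- which.max(fw$head$probs)
  dlogits <- -fw$head$probs; dlogits[y] <- dlogits[y] + 1
  bw <- pdsgraph:::gnn_backward(fw, pl, params$schema, dlogits)
  imp <- sqrt(rowSums(bw$dX0^2))
  expect_identical(imp[6], 0)
  expect_gt(max(imp[1:4]), 0)
})

test_that("subject and group explanations assemble all components", {
  set.seed(106)
  cfg <- model_config(seed = 15)
  params <- init_params(cfg)
  fit <- structure(list(params = params, config = cfg,
                        backend = "reference"),
                   class = "pds_gnn_fit")
  gs <- replicate(3, rand_graph(cfg, label = "MSA"), simplify = FALSE)
  ex <- explain_subject(fit, gs[[1]])
  expect_s3_class(ex, "pds_explanation")
  expect_length(ex$I_node, 96)
  expect_identical(nrow(ex$retained_edges), 684L)
  expect_identical(nrow(ex$roi_report), 96L)
  expect_true(ex$predicted %in% PDS_CLASSES)

  grp <- explain_group(fit, gs)
  expect_identical(grp$n_subjects, 3L)
  expect_length(grp$mean_I_node, 96)
  # the group mean is the mean of the subject importances
  subj <- lapply(gs, function(g) explain_subject(fit, g)$I_node)
  expect_equal(grp$mean_I_node, Reduce(`+`, subj) / 3, tolerance = 1e-12)

  dir <- withr::local_tempdir()
  write_explanation(ex, dir)
  expect_true(file.exists(file.path(dir, "node_importance.tsv")))
  expect_true(file.exists(file.path(dir, "retained_edges.tsv")))
})
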