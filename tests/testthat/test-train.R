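# Training-loop mechanics on deliberately small cohorts; classification
# power on realistic sizes is exercised by the acceptance suite.

small_tc <- function(...) {
  train_config(max_epochs = 6, patience = 5, batch_size = 8, ...)
}

test_that("training is reproducible from its seeds", {
  graphs <- small_graph_cohort(n_per_class = 4, seed = 21)
  f1 <- train_gnn(graphs, model_config(seed = 2), small_tc(seed = 3))
  f2 <- train_gnn(graphs, model_config(seed = 2), small_tc(seed = 3))
  expect_identical(f1$params$theta, f2$params$theta)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  f3 <- train_gnn(graphs, model_config(seed = 2), small_tc(seed = 4))
  expect_false(identical(f1$params$theta, f3$params$theta))
})

test_that("gradient norms never exceed the clip after clipping", {
  graphs <- small_graph_cohort(n_per_class = 4, seed = 22)
  fit <- train_gnn(graphs, model_config(seed = 1), small_tc(seed = 1))
  expect_true(all(fit$history$grad_norm <= 3.0 + 1e-6))
})

test_that("the recorded learning rate follows the schedule", {
  graphs <- small_graph_cohort(n_per_class = 4, seed = 23)
  tc <- small_tc(seed = 1)
  fit <- train_gnn(graphs, model_config(seed = 1), tc)
  expect_equal(fit$history$lr,
               lr_at_step(fit$history$epoch - 1, tc), tolerance = 1e-12)
})

test_that("early stopping restores the best validation weights", {
  graphs <- small_graph_cohort(n_per_class = 5, seed = 24)
  tc <- train_config(max_epochs = 12, patience = 3, batch_size = 8,
                     seed = 2)
  fit <- train_gnn(graphs, model_config(seed = 2), tc)
  expect_equal(fit$best_val_loss, min(fit$history$val_loss),
               tolerance = 1e-12)
  expect_lte(nrow(fit$history), 12)
  # best_val_loss is attained at best_epoch
  expect_equal(fit$history$val_loss[fit$best_epoch], fit$best_val_loss,
               tolerance = 1e-12)
})

test_that("with negligible learning rate parameters are fixed points", {
  graphs <- small_graph_cohort(n_per_class = 4, seed = 25)
  mc <- model_config(seed = 5)
  init <- init_params(mc)
  tc <- train_config(max_epochs = 3, patience = 2, batch_size = 8,
                     lr_peak = 1e-16, lr_floor = 1e-18, seed = 1,
                     node_feature_dropout = 0, edge_noise_fraction = 0)
  fit <- train_gnn(graphs, mc, tc)
  expect_lt(max(abs(fit$params$theta - init$theta)), 1e-12)
})

test_that("the two-stage protocol warm-starts from stage-1 weights", {
  pre <- small_graph_cohort(n_per_class = 4, seed = 26)
  fin <- small_graph_cohort(n_per_class = 4, seed = 27)
  mc <- model_config(seed = 3)
  tc1 <- small_tc(seed = 1)
  # freeze stage 2 (negligible lr): its result must equal stage-1 weights
  tc2 <- train_config(max_epochs = 3, patience = 2, batch_size = 8,
                      lr_peak = 1e-16, lr_floor = 1e-18, seed = 2,
                      node_feature_dropout = 0, edge_noise_fraction = 0)
  two <- pretrain_finetune(pre, fin, mc, tc1, tc2)
  expect_lt(max(abs(two$params$theta - two$pretrain_fit$params$theta)),
            1e-12)
  # an empty pretraining cohort reduces to plain training
  plain <- pretrain_finetune(list(), fin, mc, tc1, tc1)
  direct <- train_gnn(fin, mc, tc1)
  expect_identical(plain$params$theta, direct$params$theta)
  expect_null(plain$pretrain_fit)
})

test_that("training validates its inputs", {
  graphs <- small_graph_cohort(n_per_class = 3, seed = 28)
  unlabelled <- graphs
  unlabelled[[1]]$label <- NULL
  expect_error(train_gnn(unlabelled, model_config(), small_tc()),
               "labelled")
  one_class <- Filter(function(g) g$label == "IPD", graphs)
  expect_error(train_gnn(one_class, model_config(), small_tc()),
               "2 classes")
  tiny <- graphs[c(1, 4, 7)] # one subject per class
  expect_error(train_gnn(tiny, model_config(), small_tc()), "empty")
})

test_that("predict returns tidy per-subject probabilities", {
  graphs <- small_graph_cohort(n_per_class = 4, seed = 29)
  fit <- train_gnn(graphs, model_config(seed = 1), small_tc(seed = 1))
  pred <- predict(fit, graphs[1:5])
  expect_s3_class(pred, "tbl_df")
  expect_identical(nrow(pred), 5L)
  probs <- as.matrix(pred[, c(".pred_IPD", ".pred_MSA", ".pred_PSP")])
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-9)
  expect_identical(pred$.pred_class,
                   c("IPD", "MSA", "PSP")[max.col(probs)])
  # tidy()/glance() expose the history and summary
  expect_identical(tidy(fit), fit$history)
  gl <- glance(fit)
  expect_identical(gl$epochs, nrow(fit$history))
  expect_identical(gl$n_parameters, length(fit$params$theta))
})

test_that("reference and compiled backends train identically", {
  graphs <- small_graph_cohort(n_per_class = 3, seed = 30)
  mc <- model_config(seed = 7)
  tc <- train_config(max_epochs = 2, patience = 1, batch_size = 9, seed = 5,
                     node_feature_dropout = 0, edge_noise_fraction = 0)
  # dropout draws differ between backends, so compare with the
  # stochastic pieces disabled
  mc$attention_dropout <- 0
  mc$head_dropout <- 0
  f_ref <- train_gnn(graphs, mc, tc, backend = "reference")
  f_cpp <- train_gnn(graphs, mc, tc, backend = "compiled")
  expect_equal(f_ref$params$theta, f_cpp$params$theta, tolerance = 1e-8)
  expect_equal(f_ref$history$val_loss, f_cpp$history$val_loss,
               tolerance = 1e-8)
})
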