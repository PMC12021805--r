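# shared test fixtures, all built in code

# a small architecture for fast oracle/gradient tests; the graph
# invariants (96 nodes) are deliberately relaxed at this internal level
toy_config <- function(n_nodes = 6L, d_model = 5L, n_layers = 2L,
                       n_heads = 2L, d_k = 3L, d_v = 4L, d_ffn = 7L,
                       head_dims = c(6L, 4L), topk_neighbors = 3L,
                       seed = 7L, ...) {
  model_config(n_nodes = n_nodes, d_model = d_model, n_layers = n_layers,
               n_heads = n_heads, d_k = d_k, d_v = d_v, d_ffn = d_ffn,
               head_dims = head_dims, topk_neighbors = topk_neighbors,
               seed = seed, ...)
}

rand_weights <- function(n) {
  A <- matrix(runif(n * n), n, n)
  W <- (A + t(A)) / 2
  diag(W) <- 1
  W
}

rand_node_features <- function(n, d) matrix(runif(n * d), n, d)

# a random labelled 96-node metabolic graph
rand_graph <- function(config = model_config(), label = NULL,
                       subject_id = "s1") {
  metabolic_graph(rand_node_features(config$n_nodes, config$d_model),
                  rand_weights(config$n_nodes),
                  subject_id = subject_id, label = label)
}

# a random radiomic table over the bundled atlas
rand_table <- function(n_features = 8L, subject_id = "s1", label = NULL) {
  vals <- matrix(runif(96 * n_features), 96, n_features)
  radiomic_table(vals, sprintf("feat_%02d", seq_len(n_features)),
                 subject_id = subject_id, label = label)
}

# small, quick cohort -> graphs helper for training tests
small_graph_cohort <- function(n_per_class = 6L, seed = 1L,
                               effect_scale = 1.0) {
  coh <- generate_cohort(cohort_spec(n_per_class = n_per_class,
                                     effect_scale = effect_scale,
                                     seed = seed))
  cohort_to_graphs(coh$tables)$graphs
}

expect_all_finite <- function(x) {
  expect_true(all(is.finite(x)))
}
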