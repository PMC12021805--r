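test_that("cohort generation is deterministic and correctly sized", {
  spec <- cohort_spec(n_per_class = 5, seed = 9)
  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(spec)
  expect_length(coh1$tables, 15)
  expect_identical(vapply(coh1$tables, `[[`, "", "label"),
                   rep(c("IPD", "MSA", "PSP"), each = 5))
  expect_identical(coh1$tables[[3]]$values, coh2$tables[[3]]$values)
  coh3 <- generate_cohort(cohort_spec(n_per_class = 5, seed = 10))
  expect_false(identical(coh1$tables[[1]]$values, coh3$tables[[1]]$values))
  # every table passes the container invariants (construction enforces)
  expect_true(all(vapply(coh1$tables, inherits, TRUE, "radiomic_table")))
})

test_that("pruning removes exactly the planted affine-copy columns", {
  coh <- generate_cohort(cohort_spec(n_per_class = 4, seed = 11))
  sel <- prune_collinear_features(coh$tables)
  copies <- pdsgraph:::synthetic_feature_catalogue()$copies
  expect_setequal(sel$dropped$dropped, copies$copy)
  expect_identical(length(sel$retained), 36L)
  # each copy is flagged against its source with |r| = 1
  for (k in seq_len(nrow(copies))) {
    row <- sel$dropped[sel$dropped$dropped == copies$copy[k], ]
    expect_identical(row$kept, copies$source[k])
    expect_equal(abs(row$r), 1, tolerance = 1e-12)
  }
})

test_that("planted mean shifts appear at the designated nodes", {
  spec <- cohort_spec(n_per_class = 30, seed = 12)
  coh <- generate_cohort(spec)
  st <- pdsgraph:::cohort_structure(spec)
  block_cols <- st$catalogue$intensity_block
  labels <- vapply(coh$tables, `[[`, "", "label")
  sig <- spec$signatures$IPD
  mean_at <- function(class) {
    vals <- vapply(coh$tables[labels == class], function(t) {
      mean(t$values[sig$hypo_nodes, block_cols])
    }, numeric(1))
    c(m = mean(vals), se = sd(vals) / sqrt(length(vals)))
  }
  ipd <- mean_at("IPD")
  msa <- mean_at("MSA")
  # IPD hypometabolic nodes sit delta * mean(scale) below the MSA level
  expected_gap <- spec$delta_hypo *
    mean(st$scale_f[match(block_cols, st$real_names)])
  gap <- ipd["m"] - msa["m"]
  se <- sqrt(ipd["se"]^2 + msa["se"]^2)
  expect_lt(abs(gap - expected_gap), 4 * se)
  expect_lt(gap, 0)
})

test_that("a zero-effect spec yields class-exchangeable subjects", {
  spec <- cohort_spec(n_per_class = 3, effect_scale = 0, seed = 13)
  st <- pdsgraph:::cohort_structure(spec)
  # same RNG stream, different class labels: identical feature tables
  set.seed(77)
  a <- generate_subject(spec, "IPD", structure = st)
  set.seed(77)
  b <- generate_subject(spec, "PSP", structure = st)
  expect_identical(a$values, b$values)
  expect_false(identical(a$label, b$label))
})

test_that("disrupted edges weaken R2SN weights where planted", {
  # Monte-Carlo over subjects: the IPD-disrupted pairs must be weaker in
  # IPD subjects than in MSA subjects (whose multiplier for those pairs
  # is 1), one-sided t-test at p < 0.01
  spec <- cohort_spec(n_per_class = 60, seed = 14)
  coh <- generate_cohort(spec)
  sel <- prune_collinear_features(coh$tables)
  graphs <- cohort_to_graphs(coh$tables, selection = sel)$graphs
  labels <- vapply(graphs, function(g) g$label, "")
  pairs <- spec$signatures$IPD$disrupted_edges
  mean_w <- function(g) mean(g$weights[pairs])
  w_ipd <- vapply(graphs[labels == "IPD"], mean_w, 0)
  w_msa <- vapply(graphs[labels == "MSA"], mean_w, 0)
  ht <- t.test(w_ipd, w_msa, alternative = "less")
  expect_lt(ht$p.value, 0.01)

  # effect localization: group-average difference concentrates on the
  # class's signature pairs rather than on untracked edges
  g_ipd <- group_average_network(graphs[labels == "IPD"])
  g_msa <- group_average_network(graphs[labels == "MSA"])
  D <- abs(g_ipd$weights - g_msa$weights)
  sig_pairs <- rbind(spec$signatures$IPD$disrupted_edges,
                     spec$signatures$IPD$enhanced_edges,
                     spec$signatures$MSA$disrupted_edges,
                     spec$signatures$MSA$enhanced_edges)
  tracked <- matrix(FALSE, 96, 96)
  tracked[sig_pairs] <- TRUE
  tracked <- tracked | t(tracked)
  off <- upper.tri(D)
  expect_gt(mean(D[tracked & off]), 3 * mean(D[!tracked & off]))
})

test_that("class separability grows with the planted effect size", {
  # AUC of a one-dimensional probe (mean intensity over the class's
  # hypometabolic nodes) is non-decreasing in effect_scale
  aucs <- vapply(c(0, 0.5, 1), function(es) {
    spec <- cohort_spec(n_per_class = 20, effect_scale = es, seed = 15)
    coh <- generate_cohort(spec)
    labels <- vapply(coh$tables, `[[`, "", "label")
    block <- pdsgraph:::synthetic_feature_catalogue()$intensity_block
    nodes <- spec$signatures$PSP$hypo_nodes
    score <- vapply(coh$tables, function(t) {
      -mean(t$values[nodes, block])
    }, numeric(1))
    pos <- score[labels == "PSP"]
    neg <- score[labels != "PSP"]
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  }, numeric(1))
  expect_true(all(diff(aucs) >= -0.02))
  expect_gt(aucs[3], 0.9)
  expect_lt(abs(aucs[1] - 0.5), 0.15)
})

test_that("ground truth round-trips through its JSON report", {
  coh <- generate_cohort(cohort_spec(n_per_class = 2, seed = 16))
  path <- withr::local_tempfile(fileext = ".json")
  ground_truth_report(coh, path)
  got <- read_ground_truth(path)
  expect_named(got, c("IPD", "MSA", "PSP"))
  for (cl in names(got)) {
    expect_identical(got[[cl]]$hypo_nodes, coh$truth[[cl]]$hypo_nodes)
    expect_identical(got[[cl]]$hyper_nodes, coh$truth[[cl]]$hyper_nodes)
    expect_identical(got[[cl]]$disrupted_edges,
                     unname(coh$truth[[cl]]$disrupted_edges))
    expect_true(all(unlist(got[[cl]][c("hypo_nodes", "hyper_nodes")]) %in%
                      1:96))
  }
})

test_that("cohort directories round-trip through the table readers", {
  coh <- generate_cohort(cohort_spec(n_per_class = 2, seed = 17))
  dir <- withr::local_tempdir()
  write_cohort_dir(coh, dir)
  got <- read_cohort_dir(dir)
  expect_length(got$tables, 6)
  expect_identical(got$tables[[4]]$values, coh$tables[[4]]$values)
  expect_identical(got$tables[[4]]$label, coh$tables[[4]]$label)
})
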