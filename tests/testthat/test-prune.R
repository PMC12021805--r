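# helper: a pair of feature columns with an exact sample correlation r,
# built by Gram-Schmidt on iid normals
column_pair_with_r <- function(n, r) {
  u <- scale(rnorm(n))[, 1]
  v <- rnorm(n)
  v <- scale(v - u * sum(u * v) / sum(u * u))[, 1]
  cbind(x = u, y = r * u + sqrt(1 - r^2) * v)
}

cohort_from_matrix <- function(X, n_subjects = 2) {
  # split stacked (subject x region) rows back into per-subject tables
  lapply(seq_len(n_subjects), function(s) {
    rows <- (s - 1) * 96 + seq_len(96)
    radiomic_table(X[rows, , drop = FALSE], colnames(X),
                   subject_id = paste0("s", s))
  })
}

test_that("perfect and near-threshold collinearity is pruned at r > 0.9", {
  set.seed(10)
  n <- 2 * 96
  base <- matrix(rnorm(n * 2), n, 2)
  p91 <- column_pair_with_r(n, 0.91)
  p89 <- column_pair_with_r(n, 0.89)
  X <- cbind(base, p91, p89)
  colnames(X) <- c("A", "B_exact", "x91", "y91", "x89", "y89")
  X[, "B_exact"] <- 2 * X[, "A"] + 3 # r = 1 with A
  cohort <- cohort_from_matrix(X)
  sel <- prune_collinear_features(cohort)
  expect_false("B_exact" %in% sel$retained) # r = 1 dropped
  expect_true("A" %in% sel$retained)
  expect_false("y91" %in% sel$retained) # |r| = 0.91 > 0.9: later one dropped
  expect_true(all(c("x91", "x89", "y89") %in% sel$retained)) # 0.89 kept
  b <- sel$dropped[sel$dropped$dropped == "B_exact", ]
  expect_equal(b$kept, "A")
  expect_equal(abs(b$r), 1, tolerance = 1e-12)
})

test_that("retained set matches a brute-force greedy oracle", {
  set.seed(11)
  n <- 3 * 96
  X <- matrix(rnorm(n * 9), n, 9)
  # three planted near-duplicates of earlier columns
  X <- cbind(X, X[, 2] + rnorm(n, 0, 0.05), X[, 5] + rnorm(n, 0, 0.05),
             X[, 7] + rnorm(n, 0, 0.05))
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  cohort <- cohort_from_matrix(X, 3)
  sel <- prune_collinear_features(cohort, threshold = 0.9)

  # independent oracle: all-pairs Pearson + the same greedy rule,
  # written with explicit loops
  R <- matrix(NA_real_, ncol(X), ncol(X))
  for (i in seq_len(ncol(X))) {
    for (j in seq_len(ncol(X))) R[i, j] <- cor(X[, i], X[, j])
  }
  kept <- integer(0)
  for (j in seq_len(ncol(X))) {
    if (!any(abs(R[j, kept]) > 0.9)) kept <- c(kept, j)
  }
  expect_identical(sel$retained, colnames(X)[kept])
  # every retained pair is below the threshold
  expect_lte(max(abs(R[kept, kept][upper.tri(diag(length(kept)))])), 0.9)
})

test_that("pruning is idempotent", {
  set.seed(12)
  X <- matrix(rnorm(2 * 96 * 8), 2 * 96, 8)
  X <- cbind(X, X[, 1] * 1.5 + 2)
  colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  cohort <- cohort_from_matrix(X)
  sel1 <- prune_collinear_features(cohort)
  pruned <- lapply(cohort, minmax_normalize, selection = sel1)
  sel2 <- prune_collinear_features(pruned)
  expect_identical(sel2$retained, sel1$retained)
  expect_equal(nrow(sel2$dropped), 0)
})

test_that("zero-variance features are dropped with an undefined-r flag", {
  set.seed(13)
  X <- matrix(rnorm(2 * 96 * 3), 2 * 96, 3)
  X <- cbind(X, const = 5)
  colnames(X) <- c("a", "b", "c", "const")
  sel <- prune_collinear_features(cohort_from_matrix(X))
  expect_false("const" %in% sel$retained)
  row <- sel$dropped[sel$dropped$dropped == "const", ]
  expect_true(is.na(row$r))
})

test_that("selection cannot be fit on a single subject", {
  expect_error(prune_collinear_features(list(rand_table(4))), "cohort")
})

test_that("selection JSON round-trips", {
  set.seed(14)
  X <- matrix(rnorm(2 * 96 * 5), 2 * 96, 5)
  X <- cbind(X, dup = X[, 3])
  colnames(X) <- c(sprintf("f%d", 1:5), "dup")
  sel <- prune_collinear_features(cohort_from_matrix(X))
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_selection(sel, path)
  got <- read_feature_selection(path)
  expect_identical(got$retained, sel$retained)
  expect_equal(got$dropped$r, sel$dropped$r, tolerance = 1e-15)
  expect_identical(got$threshold, sel$threshold)
})

test_that("min-max normalization matches the direct formula", {
  set.seed(15)
  tab <- rand_table(6)
  norm <- minmax_normalize(tab)
  for (j in seq_len(6)) {
    col <- tab$values[, j]
    expect_equal(norm$values[, j],
                 setNames((col - min(col)) / (max(col) - min(col)),
                          names(col)),
                 tolerance = 1e-15)
  }
  expect_true(all(norm$values >= 0 & norm$values <= 1))
  # endpoints: a constructed column hits exactly 0, 0.5, 1
  v <- tab$values
  v[, 1] <- rep(c(2, 4, 6), each = 32)
  tab2 <- radiomic_table(v, tab$feature_names)
  n2 <- minmax_normalize(tab2)
  expect_setequal(unique(as.vector(n2$values[, 1])), c(0, 0.5, 1))
})

test_that("constant columns normalize to 0 with a warning", {
  tab <- rand_table(3)
  v <- tab$values
  v[, 2] <- 5
  tab <- radiomic_table(v, tab$feature_names)
  expect_warning(norm <- minmax_normalize(tab), "constant")
  expect_true(all(norm$values[, 2] == 0))
})

test_that("normalization is invariant to positive affine feature rescaling", {
  set.seed(16)
  tab <- rand_table(5)
  a <- runif(5, 0.2, 4)
  b <- rnorm(5)
  scaled <- radiomic_table(sweep(sweep(tab$values, 2, a, "*"), 2, b, "+"),
                           tab$feature_names)
  expect_equal(minmax_normalize(scaled)$values, minmax_normalize(tab)$values,
               tolerance = 1e-12)
})
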