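#' Confusion matrix over the three diagnostic classes
#'
#' @param truth true class labels.
#' @param pred predicted class labels.
#' @return 3x3 integer matrix; entry `(c, c')` counts class-`c` subjects
#'   predicted as `c'`.
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  assert_classes(truth, "truth")
  assert_classes(pred, "pred")
  table(factor(truth, PDS_CLASSES), factor(pred, PDS_CLASSES)) |>
    unclass() |> `dimnames<-`(list(truth = PDS_CLASSES, pred = PDS_CLASSES))
}

#' Per-class recall, precision and F1 from a confusion matrix
#'
#' Percent-scale metrics in the published reporting convention:
#' `recall_c = TP / row sum`, `precision_c = TP / column sum`, F1 the
#' harmonic mean.  A class with zero support or zero predictions gets 0
#' for the undefined metric (never NaN), flagged in the `flag` column.
#'
#' @param confusion square count matrix (classes in [PDS_CLASSES] order).
#' @return A `pds_metrics` tibble: one row per class with `support`,
#'   `recall`, `precision`, `f1` (percent) and `flag`; the confusion
#'   matrix and overall accuracy are attached as attributes.
#' @export
per_class_prf <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  classes <- rownames(confusion) %||% PDS_CLASSES[seq_len(nrow(confusion))]
  tp <- diag(confusion)
  supp <- rowSums(confusion)
  predn <- colSums(confusion)
  recall <- ifelse(supp > 0, tp / supp, 0)
  precision <- ifelse(predn > 0, tp / predn, 0)
  f1 <- ifelse(recall + precision > 0,
               2 * recall * precision / (recall + precision), 0)
  flag <- dplyr::case_when(
    supp == 0 ~ "zero_support",
    predn == 0 ~ "zero_predictions",
    .default = ""
  )
  out <- tibble::tibble(class = classes,
                        support = as.integer(unname(supp)),
                        recall = 100 * unname(recall),
                        precision = 100 * unname(precision),
                        f1 = 100 * unname(f1), flag = unname(flag))
  attr(out, "confusion") <- confusion
  attr(out, "accuracy") <- 100 * sum(tp) / sum(confusion)
  class(out) <- c("pds_metrics", class(out))
  out
}

#' Evaluate a fitted model on labelled graphs
#'
#' @param fit a `pds_gnn_fit`.
#' @param graphs list of labelled [metabolic_graph()].
#' @return A `pds_metrics` tibble (see [per_class_prf()]).
#' @export
evaluate_model <- function(fit, graphs) {
  pred <- predict(fit, graphs)
  if (anyNA(pred$label)) abort("evaluation graphs must be labelled")
  per_class_prf(confusion_matrix(pred$label, pred$.pred_class))
}

#' Macro-averaged F1 (fraction scale)
#'
#' @param metrics a `pds_metrics`.
#' @return mean per-class F1 / 100.
#' @export
macro_f1 <- function(metrics) mean(metrics$f1) / 100

#' Aggregate per-class metrics over repeated runs
#'
#' Sample mean and sample standard deviation per class and metric over
#' independent runs (different seeds), formatted in the `"xx.x +/- x.x"`
#' reporting convention.  With a single run the sd is reported absent.
#'
#' @param metrics_list list of `pds_metrics` from repeated runs.
#' @return A tibble with `class`, `metric`, `mean`, `sd`, `formatted`
#'   and `n_runs`; the aggregation unit (seeds) is explicit in the
#'   `unit` column.
#' @export
aggregate_over_seeds <- function(metrics_list) {
  stopifnot(length(metrics_list) >= 1L)
  long <- dplyr::bind_rows(lapply(seq_along(metrics_list), function(i) {
    m <- metrics_list[[i]]
    tidyr::pivot_longer(m[, c("class", "recall", "precision", "f1")],
                        -"class", names_to = "metric") |>
      dplyr::mutate(run = i)
  }))
  out <- long |>
    dplyr::group_by(.data$class, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
                     n_runs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      formatted = ifelse(is.na(.data$sd),
                         sprintf("%.1f", .data$mean),
                         sprintf("%.1f ± %.1f", .data$mean, .data$sd)),
      unit = "seeds"
    )
  out
}

#' Parse a formatted metric cell back to numbers
#'
#' Inverse of the `"xx.x +/- x.x"` formatting used by
#' [aggregate_over_seeds()].
#'
#' @param cell character cell like `"91.8 ± 1.6"`.
#' @return named numeric vector `c(mean, sd)` (sd `NA` when absent).
#' @export
parse_metric_cell <- function(cell) {
  parts <- strsplit(trimws(cell), "±", fixed = TRUE)[[1]]
  c(mean = as.numeric(parts[1]),
    sd = if (length(parts) > 1) as.numeric(parts[2]) else NA_real_)
}

#' Stratified train/validation/test split
#'
#' Deterministic per seed; class proportions preserved within one
#' subject per partition (largest-remainder allocation); partitions are
#' disjoint and exhaustive.
#'
#' @param labels class label per subject (or a list of labelled objects).
#' @param fractions numeric vector summing to 1, one entry per partition
#'   (default 70/15/15).
#' @param seed split seed.
#' @return A list of integer index vectors, named after
#'   `names(fractions)` or `train`/`val`/`test`.
#' @export
stratified_split <- function(labels, fractions = c(train = 0.7, val = 0.15,
                                                   test = 0.15),
                             seed = 1L) {
  if (is.list(labels)) {
    labels <- vapply(labels, function(x) x$label %||% NA_character_,
                     character(1))
  }
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  K <- length(fractions)
  nm <- names(fractions) %||% paste0("part", seq_len(K))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  parts <- setNames(vector("list", K), nm)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    if (n < K) {
      abort(sprintf("class %s has %d subjects, fewer than %d partitions",
                    cl, n, K))
    }
    base <- floor(fractions * n)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(fractions * n - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    # guarantee non-emptiness for every partition
    while (any(base == 0)) {
      give <- which.max(base)
      take <- which(base == 0)[1]
      base[give] <- base[give] - 1
      base[take] <- 1
    }
    stop_at <- cumsum(base)
    start_at <- c(1, head(stop_at, -1) + 1)
    for (k in seq_len(K)) {
      parts[[k]] <- c(parts[[k]], idx[seq(start_at[k], stop_at[k])])
    }
  }
  lapply(parts, sort)
}

#' Paired t-test on per-seed F1 vectors
#'
#' Convenience wrapper comparing two models' per-seed macro-F1 values.
#'
#' @param f1_a,f1_b numeric vectors of per-seed F1, paired by seed.
#' @return tibble with the mean difference, t statistic, df and p value.
#' @export
paired_f1_test <- function(f1_a, f1_b) {
  ht <- stats::t.test(f1_a, f1_b, paired = TRUE)
  tibble::tibble(mean_diff = unname(ht$estimate),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value)
}
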