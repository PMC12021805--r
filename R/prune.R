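#' Prune collinear radiomic features on a training cohort
#'
#' Pairwise Pearson correlations are computed over observations formed by
#' stacking every (subject, region) row of the cohort.  Features are then
#' scanned greedily in catalogue (column) order: a feature is dropped iff
#' its absolute correlation with an earlier *retained* feature exceeds
#' `threshold`.  The selection is fit once on a training cohort and must
#' be applied unchanged to validation/test subjects.
#'
#' Zero-variance features are dropped with an undefined correlation flag
#' (`r = NA`) since Pearson correlation is undefined for them.
#'
#' @param cohort list of [radiomic_table()] sharing the same features.
#' @param threshold absolute-correlation threshold above which the later
#'   feature of a pair is deemed redundant (default 0.9).
#' @return A `feature_selection`: `retained` (ordered names), `dropped`
#'   (tibble with columns `dropped`, `kept`, `r`) and `threshold`.
#' @export
prune_collinear_features <- function(cohort, threshold = 0.9) {
  if (!is.list(cohort) || length(cohort) < 2L) {
    abort("feature selection must be fit on a cohort of at least 2 subjects")
  }
  feats <- cohort[[1L]]$feature_names
  for (t in cohort) {
    if (!identical(t$feature_names, feats)) {
      abort("all tables in the cohort must share the same feature names")
    }
  }
  X <- do.call(rbind, lapply(cohort, function(t) t$values))
  sds <- apply(X, 2L, sd)
  R <- suppressWarnings(cor(X))

  retained <- character(0)
  dropped <- list()
  for (j in seq_along(feats)) {
    if (sds[j] == 0) {
      dropped[[length(dropped) + 1L]] <-
        tibble::tibble(dropped = feats[j], kept = NA_character_, r = NA_real_)
      next
    }
    hit <- NA_character_; hit_r <- NA_real_
    for (k in retained) {
      r <- R[feats[j], k]
      if (is.finite(r) && abs(r) > threshold) { hit <- k; hit_r <- r; break }
    }
    if (is.na(hit)) {
      retained <- c(retained, feats[j])
    } else {
      dropped[[length(dropped) + 1L]] <-
        tibble::tibble(dropped = feats[j], kept = hit, r = hit_r)
    }
  }
  structure(
    list(retained = retained,
         dropped = if (length(dropped)) dplyr::bind_rows(dropped)
                   else tibble::tibble(dropped = character(), kept = character(),
                                       r = double()),
         threshold = threshold),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d retained, %d dropped (|r| > %g)\n",
              length(x$retained), nrow(x$dropped), x$threshold))
  invisible(x)
}

#' Min-max normalize a radiomic table within a subject
#'
#' Restricts the table to the retained feature set, then rescales each
#' feature column to `(x - min) / (max - min)` across the subject's 96
#' regions, so every feature lives on `[0, 1]` within the subject.
#' A constant column maps to all zeros (with a warning) rather than NaN.
#'
#' @param table a [radiomic_table()].
#' @param selection a `feature_selection` from [prune_collinear_features()],
#'   or `NULL` to keep all features.
#' @return A normalized [radiomic_table()] restricted to retained features.
#' @export
minmax_normalize <- function(table, selection = NULL) {
  stopifnot(inherits(table, "radiomic_table"))
  keep <- if (is.null(selection)) table$feature_names else selection$retained
  missing <- setdiff(keep, table$feature_names)
  if (length(missing)) {
    abort(sprintf("table lacks retained feature(s): %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  V <- table$values[, keep, drop = FALSE]
  mins <- apply(V, 2L, min)
  maxs <- apply(V, 2L, max)
  rng <- maxs - mins
  flat <- rng == 0
  if (any(flat)) {
    warn(sprintf("constant feature column(s) normalized to 0: %s",
                 paste(keep[flat], collapse = ", ")))
    rng[flat] <- 1
  }
  Vn <- sweep(sweep(V, 2L, mins, "-"), 2L, rng, "/")
  Vn[, flat] <- 0
  out <- table
  out$values <- Vn
  out$feature_names <- keep
  out
}

#' Write a feature selection to JSON
#'
#' Selections are fit once on a training cohort and frozen; the JSON
#' form lets them be applied unchanged to later cohorts.
#'
#' @param selection a `feature_selection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_selection <- function(selection, path) {
  stopifnot(inherits(selection, "feature_selection"))
  jsonlite::write_json(
    list(retained = selection$retained,
         dropped = selection$dropped,
         threshold = selection$threshold),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a feature selection written by [write_feature_selection()]
#'
#' @param path JSON file.
#' @return A `feature_selection`.
#' @export
read_feature_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dropped <- tibble::as_tibble(obj$dropped)
  if (nrow(dropped) == 0L) {
    dropped <- tibble::tibble(dropped = character(), kept = character(),
                              r = double())
  }
  structure(list(retained = obj$retained, dropped = dropped,
                 threshold = obj$threshold),
            class = "feature_selection")
}
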