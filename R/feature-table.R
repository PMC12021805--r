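#' Construct a per-subject radiomic feature table
#'
#' A radiomic table holds one subject's region-by-feature matrix: one row
#' per atlas region (in atlas order), one column per radiomic feature
#' (intensity, texture, shape descriptors extracted per region).
#'
#' @param values numeric matrix, 96 regions x F features, no missing values.
#' @param feature_names character vector of length F.
#' @param subject_id subject identifier.
#' @param label optional diagnosis, one of `"IPD"`, `"MSA"`, `"PSP"`.
#' @param atlas atlas tibble the rows are aligned to.
#' @return An object of class `radiomic_table`.
#' @export
radiomic_table <- function(values, feature_names, subject_id = "subject",
                           label = NULL, atlas = default_atlas()) {
  validate_atlas(atlas)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(atlas)) {
    abort(sprintf("expected %d region rows, got %d", nrow(atlas), nrow(values)))
  }
  if (ncol(values) < 2L) abort("need at least 2 features")
  if (length(feature_names) != ncol(values)) {
    abort("feature_names length must match number of columns")
  }
  if (anyDuplicated(feature_names)) abort("feature names must be unique")
  if (anyNA(values) || !all(is.finite(values))) {
    abort("feature values must be finite and non-missing")
  }
  dimnames(values) <- list(atlas$name, feature_names)
  if (!is.null(label)) assert_classes(label)
  structure(
    list(subject_id = as.character(subject_id), values = values,
         feature_names = as.character(feature_names),
         label = if (is.null(label)) NULL else as.character(label)),
    class = "radiomic_table"
  )
}

#' @export
print.radiomic_table <- function(x, ...) {
  cat(sprintf("<radiomic_table> subject %s: %d regions x %d features%s\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @method as_tibble radiomic_table
#' @export
as_tibble.radiomic_table <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "region")
}

#' Read a radiomic feature table from delimited text
#'
#' Expects a header row of feature names; the first column identifies the
#' region by atlas name or 1-based atlas index.  Rows are reordered to
#' atlas order.  The delimiter is taken from the file extension
#' (`.tsv` = tab, otherwise comma); parsing uses the dot decimal mark
#' regardless of locale.
#'
#' @param path CSV or TSV file.
#' @param atlas atlas tibble.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param label optional diagnosis label.
#' @return A [radiomic_table()].
#' @export
read_feature_table <- function(path, atlas = default_atlas(),
                               subject_id = NULL, label = NULL) {
  validate_atlas(atlas)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = "."), progress = FALSE
  )
  if (ncol(df) < 3L) abort(sprintf("%s: need a region column plus >= 2 features", path))
  region_col <- df[[1L]]
  feature_names <- names(df)[-1L]

  # region keys may be names or 1-based indices
  if (all(grepl("^[0-9]+$", region_col))) {
    idx <- as.integer(region_col)
    bad <- setdiff(idx, atlas$index)
    if (length(bad)) abort(sprintf("%s: region index not in atlas: %s",
                                   path, paste(bad, collapse = ", ")))
    keys <- atlas$name[idx]
  } else {
    keys <- region_col
    bad <- setdiff(keys, atlas$name)
    if (length(bad)) abort(sprintf("%s: region not in atlas: %s",
                                   path, paste(head(bad, 5L), collapse = ", ")))
  }
  dup <- keys[duplicated(keys)]
  if (length(dup)) abort(sprintf("%s: duplicate region(s): %s",
                                 path, paste(unique(dup), collapse = ", ")))
  missing <- setdiff(atlas$name, keys)
  if (length(missing)) abort(sprintf("%s: missing region(s): %s",
                                     path, paste(head(missing, 5L), collapse = ", ")))

  values <- matrix(NA_real_, nrow(df), length(feature_names))
  for (j in seq_along(feature_names)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      i <- which(is.na(num))[1L]
      abort(sprintf("%s: non-numeric cell at row %d, column '%s': '%s'",
                    path, i, feature_names[j], col[i]))
    }
    values[, j] <- num
  }
  values <- values[match(atlas$name, keys), , drop = FALSE]
  radiomic_table(values, feature_names,
                 subject_id = subject_id %||%
                   tools::file_path_sans_ext(basename(path)),
                 label = label, atlas = atlas)
}

#' Write a radiomic feature table to delimited text
#'
#' Inverse of [read_feature_table()]; values are written at full double
#' precision so the round trip is exact.
#'
#' @param table a [radiomic_table()].
#' @param path output path; `.tsv` writes tab-separated, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "radiomic_table"))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region", table$feature_names), collapse = delim), con)
  rows <- vapply(seq_len(nrow(table$values)), function(i) {
    paste(c(rownames(table$values)[i],
            sprintf("%.17g", table$values[i, ])), collapse = delim)
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}
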