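#' @useDynLib pdsgraph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif pnorm dnorm sd cor var setNames
#' @importFrom utils head tail
NULL

# class labels used throughout; order fixed so confusion matrices,
# one-hot encodings and reports always agree
PDS_CLASSES <- c("IPD", "MSA", "PSP")

assert_classes <- function(labels, arg = "label") {
  bad <- setdiff(unique(labels), PDS_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s value(s): %s (expected %s)",
                  arg, paste(bad, collapse = ", "),
                  paste(PDS_CLASSES, collapse = "/")))
  }
  invisible(labels)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_symmetric <- function(m, tol = 1e-8, arg = "weights") {
  if (!is_square(m)) abort(sprintf("%s must be a square matrix", arg))
  if (max(abs(m - t(m))) > tol) abort(sprintf("%s must be symmetric", arg))
  invisible(m)
}

#' Exact Gaussian-CDF GELU activation
#'
#' `gelu(x) = x * pnorm(x)`; the exact form (not the tanh approximation)
#' is used throughout so that analytic gradients and brute-force oracles
#' agree to machine precision.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape as `x`.
#' @keywords internal
gelu <- function(x) x * pnorm(x)

# derivative of exact GELU
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically safe row-wise softmax; -Inf entries (masked) map to 0.
# max.col is C-level, much faster than apply(S, 1, max).
softmax_rows <- function(S) {
  n <- nrow(S)
  rmax <- S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
  E <- exp(S - rmax)
  E[!is.finite(E)] <- 0 # exp(-Inf - finite) underflow guard
  E / rowSums(E)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
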