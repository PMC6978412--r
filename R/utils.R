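`%||%` <- function(x, y) if (is.null(x)) y else x

#' Numerically safe softplus
#'
#' `log(1 + exp(x))`, evaluated without overflow for large `x`. Used by the
#' synthetic generator as the link mapping latent Gaussian expression onto a
#' non-negative TPM scale; it is strictly increasing, so rank-based statistics
#' are unaffected by it.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape as `x`, elementwise `log(1 + exp(x))`.
#' @export
#' @examples
#' softplus(c(-10, 0, 10))
softplus <- function(x) {
  out <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  if (is.matrix(x)) {
    out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  }
  out
}

# Centre each row and scale it to unit Euclidean norm; constant rows become
# all-zero rows (their index is returned in attr "constant_rows").
row_standardise <- function(x) {
  ctr <- x - rowMeans(x)
  ss <- sqrt(rowSums(ctr^2))
  constant <- which(ss == 0 | !is.finite(ss))
  ss[ss == 0 | !is.finite(ss)] <- 1
  out <- ctr / ss
  attr(out, "constant_rows") <- constant
  out
}

# Mid-ranks of each row of a matrix (ties get average ranks).
row_ranks <- function(x) {
  t(apply(x, 1L, rank, ties.method = "average"))
}

# Reindex a sparse matrix onto a new row universe; rows absent from `m`
# become all-zero. Rows of `m` outside `ids` are dropped.
expand_sparse_rows <- function(m, ids) {
  out <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(length(ids), ncol(m)), dimnames = list(ids, colnames(m))
  )
  shared <- intersect(rownames(m), ids)
  out[shared, ] <- m[shared, , drop = FALSE]
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_no_duplicates <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stopf("duplicate %s: %s", what, paste(head(dup, 5L), collapse = ", "))
  }
  invisible(ids)
}

# Derive a stream of reproducible sub-seeds from one user seed, kept inside
# the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}
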