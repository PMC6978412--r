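#' Spearman correlation of query entities against reference genes
#'
#' Each row of `query` (a gene or isoform expression profile) is correlated
#' against every row of `reference` across the shared samples. Spearman's
#' rho is computed as the Pearson correlation of mid-ranks (ties receive
#' average ranks): rows are rank-transformed, centred and scaled to unit
#' norm, and the correlation matrix is a single crossproduct, so the cost is
#' one rank pass per row plus a dense matrix product.
#'
#' Rows with zero rank variance (constant expression) have undefined
#' Spearman correlation; they are assigned rho = 0 for every pair and listed
#' in the `constant_queries` / `constant_references` attributes of the
#' result.
#'
#' @param query expression matrix, queries x samples.
#' @param reference expression matrix, reference genes x samples; must have
#'   the same sample ids in the same order as `query`, and at least 3
#'   samples.
#' @return numeric matrix of correlations (queries x reference genes), all
#'   entries in `[-1, 1]`, with attributes `constant_queries` and
#'   `constant_references` naming flagged rows.
#' @export
#' @examples
#' x <- rbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
#' colnames(x) <- paste0("s", 1:4)
#' spearman_correlation(x, x)
spearman_correlation <- function(query, reference = query) {
  validate_expression(query)
  validate_expression(reference)
  if (!identical(colnames(query), colnames(reference))) {
    stopf("query and reference must share identical sample ids in order")
  }
  if (ncol(query) < 3) stopf("need >= 3 samples for rank correlation")
  q <- row_standardise(row_ranks(query))
  r <- row_standardise(row_ranks(reference))
  rho <- tcrossprod(q, r)
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  attr(rho, "constant_queries") <- rownames(query)[attr(q, "constant_rows")]
  attr(rho, "constant_references") <- rownames(reference)[attr(r, "constant_rows")]
  rho
}

#' Per-term Wilcoxon rank-sum z-scores from a correlation matrix
#'
#' For every query entity and every GO term, contrasts the query's
#' correlations with the genes annotated to the term against its
#' correlations with the non-annotated genes, using the two-sample Wilcoxon
#' rank-sum (Mann-Whitney) statistic under the normal approximation with
#' tie-corrected variance. Positive z means the annotated genes'
#' correlations are stochastically larger — coexpression evidence that the
#' query has the function.
#'
#' When the query is itself a reference gene it is excluded from its own
#' comparison; for isoform queries, supply `query_genes` so that the
#' isoform's host gene is excluded instead (controlled by `exclude_self`).
#' Terms left with fewer than 2 annotated or 2 non-annotated reference genes
#' after exclusion are recorded as `NA` and a single warning reports how
#' many scores were degenerate. If the tie correction drives the rank
#' variance to zero (all correlations tied), the z-score is 0.
#'
#' The implementation ranks each query row once and obtains all per-term
#' rank sums through one sparse matrix product with the annotation
#' membership matrix, which is what makes scoring thousands of terms
#' tractable; it is exactly equivalent to the scalar rank-sum computation.
#'
#' @param corr correlation matrix from [spearman_correlation()]
#'   (queries x reference genes).
#' @param ann [annotation_set()] indexed on the reference genes (extra
#'   annotated entities are ignored; reference genes absent from `ann` count
#'   as non-annotated).
#' @param exclude_self drop the query's own reference gene (or its host
#'   gene) from the comparison. Default `TRUE`.
#' @param query_genes optional named character vector mapping query ids to
#'   the reference gene to exclude (e.g. an isoform's host gene). When
#'   `NULL`, a query is matched to the reference gene with the same id.
#' @param continuity apply the 0.5 continuity correction to the normal
#'   approximation. Default `FALSE`: with tens of annotated and thousands of
#'   non-annotated genes the approximation is deep in its asymptotic regime.
#' @return numeric matrix of z-scores (queries x terms), `NA` where
#'   degenerate, with attribute `n_degenerate`.
#' @export
wilcoxon_zscores <- function(corr, ann, exclude_self = TRUE,
                             query_genes = NULL, continuity = FALSE) {
  stopifnot(is.matrix(corr), inherits(ann, "annotation_set"))
  refs <- colnames(corr)
  if (is.null(refs)) stopf("correlation matrix needs reference gene names")
  # membership restricted to the reference gene space
  m <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(length(refs), ncol(ann$pairs)),
    dimnames = list(refs, colnames(ann$pairs))
  )
  shared <- intersect(rownames(ann$pairs), refs)
  m[shared, ] <- ann$pairs[shared, , drop = FALSE]
  queries <- rownames(corr)
  if (is.null(query_genes)) {
    excl_idx <- match(queries, refs)
  } else {
    excl_idx <- match(unname(query_genes[queries]), refs)
  }
  if (!exclude_self) excl_idx <- rep(NA_integer_, length(queries))

  n_terms <- ncol(m)
  col_pos <- Matrix::colSums(m)
  z <- matrix(NA_real_, nrow(corr), n_terms,
              dimnames = list(queries, colnames(m)))
  n_degenerate <- 0L
  for (q in seq_len(nrow(corr))) {
    e <- excl_idx[q]
    v <- corr[q, ]
    if (!is.na(e)) v <- v[-e]
    n <- length(v)
    r <- rank(v, ties.method = "average")
    # tie term over the pooled row: sum over tie groups of t^3 - t
    cnt <- as.numeric(table(r))
    tie_term <- sum(cnt^3 - cnt)
    # rank vector padded back to full reference length (0 at the exclusion)
    rvec <- numeric(length(refs))
    rvec[if (is.na(e)) seq_along(refs) else setdiff(seq_along(refs), e)] <- r
    w <- as.numeric(rvec %*% m)
    n1 <- col_pos
    if (!is.na(e)) n1 <- n1 - m[e, ]
    n2 <- n - n1
    ok <- n1 >= 2 & n2 >= 2
    n_degenerate <- n_degenerate + sum(!ok)
    mu <- n1 * (n + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    num <- w - mu
    if (continuity) num <- num - 0.5 * sign(num)
    zq <- ifelse(sigma2 <= 0, 0, num / sqrt(pmax(sigma2, 0)))
    zq[!ok] <- NA_real_
    z[q, ] <- zq
  }
  if (n_degenerate > 0) {
    warnf("%d query-term z-score(s) degenerate (< 2 genes in a group); recorded as NA",
          n_degenerate)
  }
  attr(z, "n_degenerate") <- n_degenerate
  z
}
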