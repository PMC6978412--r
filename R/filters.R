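#' Filter GO terms by annotated-gene count
#'
#' Keeps exactly the terms annotated to between `min_genes` and `max_genes`
#' entities, both bounds inclusive. Counts must be taken on a gene-level
#' annotation set. The entity universe is unchanged, so downstream matrices
#' keep their row space. The defaults (10 and 299) restrict to terms specific
#' enough to be informative yet populated enough to score.
#'
#' @param ann an [annotation_set()] at gene level.
#' @param min_genes,max_genes inclusive bounds on the per-term annotated
#'   count.
#' @return a filtered `annotation_set` with the surviving terms, in their
#'   original order.
#' @export
filter_go_terms <- function(ann, min_genes = 10L, max_genes = 299L) {
  stopifnot(inherits(ann, "annotation_set"))
  keep <- count_filter_keep(ann$pairs, min_genes, max_genes)
  structure(
    list(
      pairs = ann$pairs[, keep, drop = FALSE],
      term_meta = ann$term_meta[keep, , drop = FALSE]
    ),
    class = "annotation_set"
  )
}

#' Filter protein domains by gene occurrence
#'
#' Keeps domains present in between `min_genes` and `max_genes` genes,
#' inclusive. Counts are taken on the gene-level domain matrix (a gene has
#' every domain carried by any of its isoforms). The defaults (6 and 500)
#' drop domains too rare to support a regression and housekeeping domains too
#' common to be function-specific.
#'
#' @param dom a gene-level [domain_annotation()].
#' @param min_genes,max_genes inclusive occurrence bounds.
#' @return a filtered `domain_annotation`.
#' @export
filter_domains <- function(dom, min_genes = 6L, max_genes = 500L) {
  stopifnot(inherits(dom, "domain_annotation"))
  keep <- count_filter_keep(dom$pairs, min_genes, max_genes)
  new_domain_annotation(dom$pairs[, keep, drop = FALSE])
}

count_filter_keep <- function(m, min_genes, max_genes) {
  if (min_genes > max_genes) stopf("min_genes (%s) > max_genes (%s)",
                                   min_genes, max_genes)
  counts <- Matrix::colSums(m != 0)
  which(counts >= min_genes & counts <= max_genes)
}

#' Aggregate isoform expression to gene expression
#'
#' A gene's TPM in each sample is the sum of the TPMs of its isoforms; no
#' expression filtering is applied. Genes appear in first-isoform order.
#'
#' @param iso_expr isoform expression matrix (isoforms x samples).
#' @param map isoform-to-gene map (see [isoform_map()]); every isoform in
#'   `iso_expr` must be mapped, otherwise an error names the orphan.
#' @return gene expression matrix (genes x samples).
#' @export
aggregate_gene_expression <- function(iso_expr, map) {
  validate_expression(iso_expr)
  map <- isoform_map(map)
  gene_of <- setNames(map$gene_id, map$isoform_id)[rownames(iso_expr)]
  orphan <- rownames(iso_expr)[is.na(gene_of)]
  if (length(orphan) > 0) {
    stopf("isoform(s) missing from map: %s",
          paste(head(orphan, 5L), collapse = ", "))
  }
  genes <- unique(unname(gene_of))
  agg <- rowsum(iso_expr, group = factor(gene_of, levels = genes),
                reorder = FALSE)
  rownames(agg) <- genes
  agg
}

#' Lift isoform domain annotation to gene level
#'
#' A gene carries a domain if any of its isoforms does (logical OR of the
#' isoform rows).
#'
#' @param iso_dom isoform-level [domain_annotation()].
#' @param map isoform-to-gene map.
#' @return gene-level `domain_annotation`.
#' @export
domains_to_genes <- function(iso_dom, map) {
  stopifnot(inherits(iso_dom, "domain_annotation"))
  map <- isoform_map(map)
  gene_of <- setNames(map$gene_id, map$isoform_id)[rownames(iso_dom$pairs)]
  orphan <- rownames(iso_dom$pairs)[is.na(gene_of)]
  if (length(orphan) > 0) {
    stopf("isoform(s) missing from map: %s",
          paste(head(orphan, 5L), collapse = ", "))
  }
  genes <- unique(unname(gene_of))
  grouping <- Matrix::sparseMatrix(
    i = match(gene_of, genes),
    j = seq_along(gene_of),
    x = 1,
    dims = c(length(genes), length(gene_of)),
    dimnames = list(genes, names(gene_of))
  )
  m <- grouping %*% iso_dom$pairs
  m@x <- rep(1, length(m@x))
  new_domain_annotation(Matrix::drop0(m))
}
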