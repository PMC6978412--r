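#' Predict GO functions for isoforms with gene-trained models
#'
#' Applies the gene-level prediction machinery to isoforms: Spearman
#' correlation of each isoform against every gene, per-term Wilcoxon z-scores
#' (excluding the isoform's own host gene from each comparison), domain
#' logits from the isoform's own domain content, and the per-term combination
#' models fusing both. The models should have been (re)fitted on the complete
#' gene set. Isoforms lacking an expression or domain row are excluded with a
#' warning.
#'
#' @param iso_expr isoform expression matrix (isoforms x samples).
#' @param gene_expr gene expression matrix (genes x samples), same samples.
#' @param iso_dom isoform-level [domain_annotation()].
#' @param ann gene-level [annotation_set()] (reference annotations).
#' @param models_domain `domain_model_set` fitted on genes.
#' @param models_combination `combination_model_set` fitted on genes.
#' @param map isoform-to-gene map.
#' @param continuity passed to [wilcoxon_zscores()].
#' @return list with `logits` (isoforms x terms combined logit matrix), `z`,
#'   `d` (the two evidence matrices).
#' @export
predict_isoform_functions <- function(iso_expr, gene_expr, iso_dom, ann,
                                      models_domain, models_combination, map,
                                      continuity = FALSE) {
  map <- isoform_map(map)
  isoforms <- rownames(iso_expr)
  no_dom <- setdiff(isoforms, rownames(iso_dom$pairs))
  if (length(no_dom) > 0) {
    warnf("%d isoform(s) lack a domain row; excluded", length(no_dom))
    isoforms <- setdiff(isoforms, no_dom)
  }
  no_map <- setdiff(isoforms, map$isoform_id)
  if (length(no_map) > 0) {
    warnf("%d isoform(s) missing from the gene map; excluded", length(no_map))
    isoforms <- setdiff(isoforms, no_map)
  }
  iso_expr <- iso_expr[isoforms, , drop = FALSE]
  host <- setNames(map$gene_id, map$isoform_id)
  corr <- spearman_correlation(iso_expr, gene_expr)
  z <- wilcoxon_zscores(corr, ann, exclude_self = TRUE,
                        query_genes = host, continuity = continuity)
  d_all <- predict_domain_logits(models_domain, iso_dom)
  d <- d_all[isoforms, colnames(z), drop = FALSE]
  logits <- predict_combined_logits(models_combination, z, d)
  list(logits = logits, z = z, d = d)
}

#' Gained / lost function calls for isoforms
#'
#' Compares each isoform's predicted logit with the term's expected
#' (prevalence) logit over genes. A term annotated to the isoform's gene is
#' called `lost` when `logit - expected` falls strictly below `lower`; a
#' non-annotated term is called `gained` when the difference rises strictly
#' above `upper`; everything else (including differences exactly at a
#' threshold) is `unchanged`.
#'
#' @param iso_logits isoform x term logit matrix.
#' @param ann gene-level [annotation_set()] (defines both the expected
#'   logits and which terms a gene is annotated to).
#' @param map isoform-to-gene map; every scored isoform must be mapped.
#' @param lower,upper thresholds on `logit - expected_logit`. Defaults -2
#'   and +2 (about a sevenfold odds change either way); both are meant to be
#'   tuned by the user.
#' @return tibble with `isoform_id`, `gene_id`, `term_id`, `annotated`,
#'   `logit`, `expected`, `delta`, `status`.
#' @export
gain_loss_calls <- function(iso_logits, ann, map, lower = -2, upper = 2) {
  stopifnot(is.matrix(iso_logits), inherits(ann, "annotation_set"))
  map <- isoform_map(map)
  host <- setNames(map$gene_id, map$isoform_id)[rownames(iso_logits)]
  if (any(is.na(host))) {
    stopf("isoform(s) without gene mapping: %s",
          paste(head(rownames(iso_logits)[is.na(host)], 5L), collapse = ", "))
  }
  meta <- term_meta(ann)
  meta <- meta[match(colnames(iso_logits), meta$term_id), ]
  n_genes <- nrow(ann$pairs)
  expected <- expected_logit(meta$n_annotated, n_genes - meta$n_annotated)
  gene_idx <- match(unname(host), rownames(ann$pairs))
  annotated <- as.matrix(ann$pairs[gene_idx, colnames(iso_logits),
                                   drop = FALSE]) > 0
  delta <- sweep(iso_logits, 2L, expected, `-`)
  status <- matrix("unchanged", nrow(delta), ncol(delta))
  status[annotated & delta < lower] <- "lost"
  status[!annotated & delta > upper] <- "gained"
  status[is.na(delta)] <- NA_character_
  tibble::tibble(
    isoform_id = rep(rownames(iso_logits), times = ncol(iso_logits)),
    gene_id = rep(unname(host), times = ncol(iso_logits)),
    term_id = rep(colnames(iso_logits), each = nrow(iso_logits)),
    annotated = as.vector(annotated),
    logit = as.vector(iso_logits),
    expected = rep(expected, each = nrow(iso_logits)),
    delta = as.vector(delta),
    status = as.vector(status)
  )
}

#' Principal-isoform consistency of isoform predictions
#'
#' For each GO term and each annotated gene with at least two isoforms,
#' checks whether the isoform with the highest predicted logit is the gene's
#' principal isoform (ties: every tied isoform counts as top, and a
#' principal among them counts as a success). A term "fulfils" the
#' consistency hypothesis under a chosen aggregation of its genes'
#' checks: `"majority"` (strictly more than half succeed), `"any-gene"`
#' (at least one), or `"all-genes"`.
#'
#' @param iso_logits isoform x term logit matrix.
#' @param ann gene-level [annotation_set()].
#' @param map isoform-to-gene map with `principal` flags.
#' @param aggregation one of `"majority"`, `"any-gene"`, `"all-genes"`.
#' @return tibble with one row per checkable term: `term_id`,
#'   `n_genes_checked`, `n_top_principal`, `fraction`, `fulfilled`; terms
#'   with no multi-isoform annotated gene carrying a principal flag are
#'   skipped and counted in attribute `n_skipped`.
#' @export
main_isoform_consistency <- function(iso_logits, ann, map,
                                     aggregation = c("majority", "any-gene",
                                                     "all-genes")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.matrix(iso_logits), inherits(ann, "annotation_set"))
  map <- isoform_map(map)
  map <- map[map$isoform_id %in% rownames(iso_logits), ]
  iso_by_gene <- split(map$isoform_id, map$gene_id)
  principal_of <- setNames(map$isoform_id[map$principal],
                           map$gene_id[map$principal])
  multi <- names(iso_by_gene)[lengths(iso_by_gene) >= 2]
  checkable <- intersect(multi, names(principal_of))
  res <- vector("list", ncol(iso_logits))
  n_skipped <- 0L
  for (j in seq_len(ncol(iso_logits))) {
    term <- colnames(iso_logits)[j]
    ann_genes <- rownames(ann$pairs)[ann$pairs[, term] != 0]
    genes <- intersect(ann_genes, checkable)
    if (length(genes) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    ok <- vapply(genes, function(g) {
      lg <- iso_logits[iso_by_gene[[g]], j]
      if (all(is.na(lg))) return(NA)
      top <- iso_by_gene[[g]][which(lg == max(lg, na.rm = TRUE))]
      principal_of[[g]] %in% top
    }, logical(1))
    ok <- ok[!is.na(ok)]
    if (length(ok) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    frac <- mean(ok)
    fulfilled <- switch(aggregation,
      "majority" = frac > 0.5,
      "any-gene" = any(ok),
      "all-genes" = all(ok)
    )
    res[[j]] <- tibble::tibble(
      term_id = term, n_genes_checked = length(ok),
      n_top_principal = sum(ok), fraction = frac, fulfilled = fulfilled
    )
  }
  out <- dplyr::bind_rows(res)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "aggregation") <- aggregation
  out
}
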