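#' Deterministic worked micro-example
#'
#' A hard-coded dataset of 12 genes (13 isoforms), 6 samples, 4 GO terms and
#' 3 domains, small enough to print yet exercising every awkward code path:
#' tied expression values, tied correlations (rank-identical module genes),
#' a constant-expression gene, a degenerate single-gene term (which triggers
#' the missing-z warning), and an isoform that loses a domain and
#' decorrelates from its gene. Regeneration is byte-identical across runs —
#' nothing is drawn from a random stream.
#'
#' Structure: terms `TA` (genes G01-G04, coexpressed, marked by domain
#' `DA`), `TB` (G05-G08, coexpressed, domain `DB` in three of four),
#' `TC` (G09 alone, degenerate), `TD` (G10-G12, uncorrelated). Gene G01 has
#' two isoforms: `G01.1` (principal, keeps `DA`) and `G01.2` (loses `DA`,
#' expression anti-correlated with the gene's pattern).
#'
#' @return the same structure as [simulate_dataset()] (without `truth`).
#' @export
worked_example_fixture <- function() {
  samples <- paste0("s", 1:6)
  fA <- c(1, 2, 3, 4, 5, 6)
  fB <- c(6, 1, 5, 2, 4, 3)
  iso_expr <- rbind(
    "G01.1" = 2 * fA,
    "G01.2" = rev(fA) / 2,
    "G02.1" = fA + 1,
    "G03.1" = 3 * fA,
    "G04.1" = fA + 0.5,
    "G05.1" = fB,
    "G06.1" = 2 * fB,
    "G07.1" = fB + 2,
    "G08.1" = 1.5 * fB,
    "G09.1" = rep(2, 6),          # constant expression
    "G10.1" = c(1, 1, 2, 2, 3, 3), # tied values
    "G11.1" = c(5, 3, 6, 1, 2, 4),
    "G12.1" = c(2, 6, 1, 5, 3, 4)
  )
  colnames(iso_expr) <- samples
  map <- tibble::tibble(
    isoform_id = rownames(iso_expr),
    gene_id = sub("\\..*$", "", rownames(iso_expr)),
    principal = !grepl("\\.2$", rownames(iso_expr))
  )
  gene_expr <- aggregate_gene_expression(iso_expr, map)
  genes <- rownames(gene_expr)
  ann <- annotation_set(
    data.frame(
      entity_id = c("G01", "G02", "G03", "G04",
                    "G05", "G06", "G07", "G08",
                    "G09",
                    "G10", "G11", "G12"),
      term_id = c(rep("TA", 4), rep("TB", 4), "TC", rep("TD", 3)),
      ontology = c(rep("BP", 4), rep("MF", 4), "CC", rep("BP", 3))
    ),
    entities = genes
  )
  iso_dom <- domain_annotation(
    data.frame(
      entity_id = c("G01.1", "G02.1", "G03.1", "G04.1",        # DA
                    "G05.1", "G06.1", "G07.1",                 # DB
                    "G02.1", "G05.1", "G10.1", "G11.1"),       # DC
      domain_id = c(rep("DA", 4), rep("DB", 3), rep("DC", 4))
    ),
    entities = rownames(iso_expr), domains = c("DA", "DB", "DC")
  )
  gene_dom <- domains_to_genes(iso_dom, map)
  list(
    iso_expr = iso_expr, gene_expr = gene_expr, annotations = ann,
    gene_domains = gene_dom, iso_domains = iso_dom, map = map
  )
}
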