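#' Read and write expression matrices
#'
#' Tab-separated text: header row holds sample ids, first column holds entity
#' ids, remaining cells hold TPM values. Reading validates the container
#' invariants (unique ids, non-negative finite values) and errors naming the
#' offending row/column; writing is the exact inverse up to numeric
#' formatting.
#'
#' @param path file path.
#' @return `read_expression()`: validated numeric matrix (entities x samples).
#' @export
read_expression <- function(path) {
  df <- read_id_matrix_tsv(path)
  if (ncol(df) < 2) stopf("expression file needs an id column and >= 1 sample")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric expression values in %s", path)
  rownames(m) <- ids
  validate_expression(m)
  m
}

#' @rdname read_expression
#' @param x numeric expression matrix with row and column names.
#' @param id_column header for the first (entity id) column.
#' @return `write_expression()`: `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "entity_id") {
  validate_expression(x)
  df <- tibble::as_tibble(x, rownames = id_column)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read annotation pair files
#'
#' Two-column tab-separated text (`entity_id`, `term_id`), with an optional
#' third column carrying the term's ontology (`CC`/`MF`/`BP`). Headerless
#' files are accepted; a header row is detected by its first field.
#'
#' @param path file path.
#' @param entities,terms optional id universes fixing order (see
#'   [annotation_set()]).
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, entities = NULL, terms = NULL) {
  df <- read_pairs(path, c("entity_id", "term_id", "ontology"))
  annotation_set(df, entities = entities, terms = terms)
}

#' @rdname read_annotations
#' @param domains optional domain id universe.
#' @return `read_domains()`: a [domain_annotation()].
#' @export
read_domains <- function(path, entities = NULL, domains = NULL) {
  df <- read_pairs(path, c("entity_id", "domain_id"))
  domain_annotation(df, entities = entities, domains = domains)
}

read_pairs <- function(path, col_names) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- identical(first[1L], col_names[1L])
  df <- utils::read.table(
    path, sep = "\t", header = has_header, colClasses = "character",
    quote = "", comment.char = ""
  )
  if (ncol(df) < 2) stopf("pair file %s needs >= 2 tab-separated columns", path)
  names(df) <- col_names[seq_len(min(ncol(df), length(col_names)))]
  df
}

#' @rdname read_annotations
#' @param ann an `annotation_set` or `domain_annotation` to serialise as a
#'   pair table.
#' @return `write_annotations()`: `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  trip <- methods::as(ann$pairs, "TsparseMatrix")
  df <- data.frame(
    entity_id = rownames(ann$pairs)[trip@i + 1L],
    term_id = colnames(ann$pairs)[trip@j + 1L],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$term_id, df$entity_id), , drop = FALSE]
  if (inherits(ann, "annotation_set") && any(!is.na(ann$term_meta$ontology))) {
    df$ontology <- ann$term_meta$ontology[match(df$term_id, ann$term_meta$term_id)]
  }
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read an isoform-to-gene map
#'
#' Tab-separated columns: isoform id, gene id, optional principal flag in
#' `{0, 1}` marking the gene's principal (most functionally representative)
#' isoform.
#'
#' @param path file path.
#' @return validated map tibble (see [isoform_map()]).
#' @export
read_isoform_map <- function(path) {
  df <- read_pairs(path, c("isoform_id", "gene_id", "principal"))
  if (!is.null(df$principal)) df$principal <- df$principal %in% c("1", "TRUE")
  isoform_map(df)
}

#' Read and write score matrices
#'
#' Real-valued entity-by-term matrices (Wilcoxon z-scores or logits) in the
#' same TSV layout as expression matrices; missing scores are `NA`.
#'
#' @param path file path.
#' @param x numeric matrix with row and column names.
#' @param id_column header for the id column.
#' @return `read_scores()`: numeric matrix; `write_scores()`: `path`,
#'   invisibly.
#' @export
write_scores <- function(x, path, id_column = "entity_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  readr::write_tsv(tibble::as_tibble(x, rownames = id_column), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read_id_matrix_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}

# TSV with a character id column followed by double columns; sample-id header
# preserved verbatim (including duplicates, which validation then rejects).
read_id_matrix_tsv <- function(path) {
  header <- names(readr::read_tsv(path, n_max = 0, show_col_types = FALSE,
                                  name_repair = "minimal"))
  ct <- readr::cols(.default = readr::col_double())
  ct$cols[[header[1L]]] <- readr::col_character()
  readr::read_tsv(path, col_types = ct, progress = FALSE,
                  name_repair = "minimal")
}
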