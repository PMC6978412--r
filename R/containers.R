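#' Validate an expression matrix
#'
#' Expression is represented as a plain numeric matrix, entities (genes or
#' isoforms) in rows and samples in columns, values in TPM. This checks the
#' container invariants: unique row and column names, and all values finite
#' and non-negative.
#'
#' @param x numeric matrix with entity row names and sample column names.
#' @return `x`, invisibly, if valid; otherwise an error naming the offender.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("expression must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("expression matrix needs entity row names and sample column names")
  }
  assert_no_duplicates(rownames(x), "entity ids")
  assert_no_duplicates(colnames(x), "sample ids")
  bad <- which(!is.finite(x) | x < 0)
  if (length(bad) > 0) {
    i <- arrayInd(bad[1L], dim(x))
    stopf(
      "expression value at entity '%s', sample '%s' is negative or non-finite",
      rownames(x)[i[1L]], colnames(x)[i[2L]]
    )
  }
  invisible(x)
}

#' Construct an annotation set
#'
#' A sparse binary entity-by-term membership container, carrying per-term
#' metadata (annotated-entity count and, optionally, the GO ontology the term
#' belongs to: `"CC"`, `"MF"` or `"BP"`).
#'
#' @param pairs data frame of membership pairs with columns `entity_id` and
#'   `term_id`, optionally `ontology`. One row per (entity, term) pair.
#' @param entities optional character vector fixing the entity universe and
#'   its order; defaults to the entities seen in `pairs`. Pairs referencing
#'   entities outside the universe are an error.
#' @param terms optional character vector fixing the term order.
#' @return an object of class `annotation_set` with fields `pairs` (sparse
#'   0/1 `Matrix`, entities x terms) and `term_meta` (tibble with `term_id`,
#'   `ontology`, `n_annotated`).
#' @export
#' @examples
#' ann <- annotation_set(
#'   data.frame(entity_id = c("G1", "G2", "G2"), term_id = c("T1", "T1", "T2"))
#' )
#' term_meta(ann)
annotation_set <- function(pairs, entities = NULL, terms = NULL) {
  pairs <- as.data.frame(pairs)
  if (!all(c("entity_id", "term_id") %in% names(pairs))) {
    stopf("`pairs` needs columns entity_id and term_id")
  }
  pairs$entity_id <- as.character(pairs$entity_id)
  pairs$term_id <- as.character(pairs$term_id)
  entities <- entities %||% unique(pairs$entity_id)
  terms <- terms %||% unique(pairs$term_id)
  assert_no_duplicates(entities, "entity ids")
  assert_no_duplicates(terms, "term ids")
  missing_e <- setdiff(pairs$entity_id, entities)
  if (length(missing_e) > 0) {
    stopf("pairs reference undeclared entities: %s",
          paste(head(missing_e, 5L), collapse = ", "))
  }
  missing_t <- setdiff(pairs$term_id, terms)
  if (length(missing_t) > 0) {
    stopf("pairs reference undeclared terms: %s",
          paste(head(missing_t, 5L), collapse = ", "))
  }
  pairs <- unique(pairs[, intersect(c("entity_id", "term_id", "ontology"),
                                    names(pairs)), drop = FALSE])
  m <- Matrix::sparseMatrix(
    i = match(pairs$entity_id, entities),
    j = match(pairs$term_id, terms),
    x = 1,
    dims = c(length(entities), length(terms)),
    dimnames = list(entities, terms)
  )
  ontology <- rep(NA_character_, length(terms))
  if ("ontology" %in% names(pairs)) {
    ont <- pairs$ontology[!is.na(pairs$ontology)]
    names(ont) <- pairs$term_id[!is.na(pairs$ontology)]
    ontology <- unname(ont[terms])
    bad <- ontology[!is.na(ontology) & !ontology %in% c("CC", "MF", "BP")]
    if (length(bad) > 0) {
      stopf("unknown ontology label(s): %s", paste(unique(bad), collapse = ", "))
    }
  }
  structure(
    list(
      pairs = m,
      term_meta = tibble::tibble(
        term_id = terms,
        ontology = ontology,
        n_annotated = as.integer(Matrix::colSums(m))
      )
    ),
    class = "annotation_set"
  )
}

# Internal: wrap an existing sparse membership matrix (already validated).
new_annotation_set <- function(m, ontology = NULL) {
  structure(
    list(
      pairs = m,
      term_meta = tibble::tibble(
        term_id = colnames(m),
        ontology = ontology %||% rep(NA_character_, ncol(m)),
        n_annotated = as.integer(Matrix::colSums(m))
      )
    ),
    class = "annotation_set"
  )
}

#' Construct a domain annotation
#'
#' Sparse binary entity-by-protein-domain presence container.
#'
#' @param pairs data frame with columns `entity_id` and `domain_id`.
#' @param entities,domains optional universes fixing order (as for
#'   [annotation_set()]).
#' @return object of class `domain_annotation` with field `pairs`
#'   (sparse 0/1 `Matrix`, entities x domains).
#' @export
domain_annotation <- function(pairs, entities = NULL, domains = NULL) {
  pairs <- as.data.frame(pairs)
  if (!all(c("entity_id", "domain_id") %in% names(pairs))) {
    stopf("`pairs` needs columns entity_id and domain_id")
  }
  names(pairs)[names(pairs) == "domain_id"] <- "term_id"
  ann <- annotation_set(pairs, entities = entities, terms = domains)
  structure(list(pairs = ann$pairs), class = "domain_annotation")
}

new_domain_annotation <- function(m) {
  structure(list(pairs = m), class = "domain_annotation")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %d entities x %d terms, %d pairs\n",
    nrow(x$pairs), ncol(x$pairs), as.integer(sum(x$pairs))
  ))
  if (any(!is.na(x$term_meta$ontology))) {
    tab <- table(x$term_meta$ontology, useNA = "no")
    cat("  ontology:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf(
    "<domain_annotation> %d entities x %d domains, %d pairs\n",
    nrow(x$pairs), ncol(x$pairs), as.integer(sum(x$pairs))
  ))
  invisible(x)
}

#' Entity, term and sample accessors
#'
#' @param x an `annotation_set`, `domain_annotation` or expression matrix.
#' @return character vector of ids.
#' @export
entity_ids <- function(x) {
  if (inherits(x, c("annotation_set", "domain_annotation"))) {
    return(rownames(x$pairs))
  }
  rownames(x)
}

#' @rdname entity_ids
#' @export
term_ids <- function(x) {
  if (inherits(x, "annotation_set")) return(x$term_meta$term_id)
  colnames(x$pairs)
}

#' Per-term metadata of an annotation set
#'
#' @param x an `annotation_set`.
#' @return tibble with `term_id`, `ontology`, `n_annotated`.
#' @export
term_meta <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  x$term_meta
}

#' Validate an isoform-to-gene map
#'
#' The map is a plain tibble with columns `isoform_id`, `gene_id` and a
#' logical `principal` flag. Every isoform maps to exactly one gene and each
#' gene has at most one principal isoform.
#'
#' @param map data frame with columns `isoform_id`, `gene_id`, and optionally
#'   `principal` (logical or 0/1; defaults to all `FALSE`).
#' @return validated tibble with the three columns.
#' @export
isoform_map <- function(map) {
  map <- tibble::as_tibble(map)
  if (!all(c("isoform_id", "gene_id") %in% names(map))) {
    stopf("map needs columns isoform_id and gene_id")
  }
  map$isoform_id <- as.character(map$isoform_id)
  map$gene_id <- as.character(map$gene_id)
  if (!"principal" %in% names(map)) map$principal <- FALSE
  map$principal <- as.logical(map$principal)
  assert_no_duplicates(map$isoform_id, "isoform ids in map")
  n_principal <- tapply(map$principal, map$gene_id, sum)
  bad <- names(n_principal)[n_principal > 1]
  if (length(bad) > 0) {
    stopf("gene(s) with more than one principal isoform: %s",
          paste(head(bad, 5L), collapse = ", "))
  }
  map[, c("isoform_id", "gene_id", "principal")]
}
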