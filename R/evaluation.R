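#' Random train/test split of entities
#'
#' Uniform random partition of the entity universe, reproducible by seed.
#'
#' @param entities character vector of entity ids.
#' @param n_test number of held-out entities (`0 < n_test < length(entities)`).
#' @param seed integer seed.
#' @return object of class `train_test_split`: list with `train`, `test`,
#'   `seed`; the two sets are disjoint and their union is `entities`.
#' @export
split_train_test <- function(entities, n_test, seed = 1L) {
  if (n_test <= 0) stopf("n_test must be positive")
  if (n_test >= length(entities)) stopf("n_test must leave a training set")
  test <- withr::with_seed(seed, sample(entities, n_test))
  structure(
    list(train = setdiff(entities, test), test = test, seed = seed),
    class = "train_test_split"
  )
}

#' @export
print.train_test_split <- function(x, ...) {
  cat(sprintf("<train_test_split> %d train / %d test (seed %d)\n",
              length(x$train), length(x$test), x$seed))
  invisible(x)
}

#' Area under the ROC curve
#'
#' The rank (Mann-Whitney) estimator: the probability that a random positive
#' scores above a random negative, with half credit for ties —
#' `P(s+ > s-) + P(s+ = s-)/2`. Undefined when only one class is present
#' (returns `NA` with a warning). `NA` scores are dropped pairwise with
#' their labels.
#'
#' @param scores numeric scores, larger = more likely positive.
#' @param labels binary labels (0/1 or logical).
#' @return AUROC in `[0, 1]`, or `NA`.
#' @export
#' @examples
#' auroc(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0)) # 0.75
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n1 <- sum(labels == 1)
  n2 <- sum(labels == 0)
  if (n1 == 0 || n2 == 0) {
    warnf("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step-curve estimator: scores are swept in descending
#' order with ties grouped into blocks; each block contributes its recall
#' increment times the precision at the block's end. For untied scores this
#' is the average-precision estimator; for completely tied (random-like)
#' scores it reduces to the class prevalence, the PR curve's random
#' baseline. Undefined without positives.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`, or `NA`.
#' @export
#' @examples
#' auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)) # 0.8333333
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels == 1)
  if (n_pos == 0) {
    warnf("AUPRC undefined: no positives")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  block_last <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(y)[block_last]
  npred <- block_last
  precision <- tp / npred
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Per-term AUROC and AUPRC of a score matrix
#'
#' Scores each GO term's column against the gene-level annotation labels,
#' typically on held-out entities only. Terms whose column is entirely
#' missing, or whose labels are single-class among the scored entities, get
#' `NA` areas (and are excluded from, but counted alongside, downstream
#' medians).
#'
#' @param scores numeric matrix (entities x terms): z-scores or logits.
#' @param ann [annotation_set()] covering the scored entities.
#' @param entities optional subset of entities to evaluate on (e.g. the test
#'   split); default all rows of `scores`.
#' @return tibble with `term_id`, `ontology`, `n_annotated` (in the full
#'   annotation set), `n_eval`, `n_pos_eval`, `auroc`, `auprc`.
#' @export
evaluate_predictions <- function(scores, ann, entities = NULL) {
  stopifnot(is.matrix(scores), inherits(ann, "annotation_set"))
  entities <- entities %||% rownames(scores)
  missing_e <- setdiff(entities, rownames(scores))
  if (length(missing_e) > 0) {
    stopf("entities not in score matrix: %s",
          paste(head(missing_e, 5L), collapse = ", "))
  }
  s <- scores[entities, , drop = FALSE]
  labels <- as.matrix(ann$pairs[entities, colnames(s), drop = FALSE])
  res <- lapply(seq_len(ncol(s)), function(j) {
    sc <- s[, j]
    y <- labels[, j]
    ok <- is.finite(sc)
    both <- sum(y[ok] == 1) > 0 && sum(y[ok] == 0) > 0
    tibble::tibble(
      term_id = colnames(s)[j],
      n_eval = sum(ok),
      n_pos_eval = as.integer(sum(y[ok] == 1)),
      auroc = if (both) auroc(sc[ok], y[ok]) else NA_real_,
      auprc = if (both && sum(y[ok] == 1) > 0) auprc(sc[ok], y[ok]) else NA_real_
    )
  })
  out <- dplyr::bind_rows(res)
  meta <- term_meta(ann)
  out <- dplyr::left_join(out, meta, by = "term_id")
  out[, c("term_id", "ontology", "n_annotated", "n_eval", "n_pos_eval",
          "auroc", "auprc")]
}

# Default GO-term size bins used for grouped performance summaries.
default_size_bins <- c(10, 20, 27, 40, 64, 114, 300)

#' Summarize per-term evaluation into a report
#'
#' Produces the overall medians, the count of terms with perfect performance
#' (both AUROC and AUPRC equal to one, up to a 1e-12 tolerance), medians by
#' GO-term size bin (first bin closed `[10,20]`, subsequent bins left-open
#' right-closed), per-ontology medians when ontology labels are present, and
#' restricted medians over terms with more than 20 and fewer than 300
#' annotated genes (for comparison against methods trained on that range).
#' Terms with undefined areas are excluded from medians and counted.
#'
#' @param per_term tibble from [evaluate_predictions()] (optionally with a
#'   `method` column to keep several methods side by side).
#' @param bins numeric bin edges over `n_annotated`.
#' @return object of class `go_eval`: list with `per_term`, `summary`,
#'   `by_bin`, `by_ontology`, `restricted` tibbles.
#' @export
summarize_evaluation <- function(per_term, bins = default_size_bins) {
  per_term <- tibble::as_tibble(per_term)
  if (!"method" %in% names(per_term)) per_term$method <- "scores"
  per_term$size_bin <- cut(per_term$n_annotated, breaks = bins,
                           include.lowest = TRUE, right = TRUE)
  scored <- dplyr::filter(per_term, !is.na(.data$auroc) & !is.na(.data$auprc))
  tol <- 1e-12
  summary <- scored |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_terms = dplyr::n(),
      median_auroc = median(.data$auroc),
      median_auprc = median(.data$auprc),
      n_perfect = sum(.data$auroc >= 1 - tol & .data$auprc >= 1 - tol),
      .groups = "drop"
    )
  n_undefined <- per_term |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n_undefined = sum(is.na(.data$auroc) | is.na(.data$auprc)),
                     .groups = "drop")
  summary <- dplyr::left_join(summary, n_undefined, by = "method")
  by_bin <- scored |>
    dplyr::group_by(.data$method, .data$size_bin) |>
    dplyr::summarise(
      n_terms = dplyr::n(),
      median_auroc = median(.data$auroc),
      median_auprc = median(.data$auprc),
      .groups = "drop"
    )
  by_ontology <- NULL
  if (any(!is.na(scored$ontology))) {
    by_ontology <- scored |>
      dplyr::filter(!is.na(.data$ontology)) |>
      dplyr::group_by(.data$method, .data$ontology) |>
      dplyr::summarise(
        n_terms = dplyr::n(),
        median_auroc = median(.data$auroc),
        median_auprc = median(.data$auprc),
        pct_perfect = 100 * mean(.data$auroc >= 1 - tol & .data$auprc >= 1 - tol),
        .groups = "drop"
      )
  }
  restricted <- scored |>
    dplyr::filter(.data$n_annotated > 20, .data$n_annotated < 300) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_terms = dplyr::n(),
      median_auroc = median(.data$auroc),
      median_auprc = median(.data$auprc),
      .groups = "drop"
    )
  structure(
    list(per_term = per_term, summary = summary, by_bin = by_bin,
         by_ontology = by_ontology, restricted = restricted, bins = bins),
    class = "go_eval"
  )
}

#' @export
print.go_eval <- function(x, ...) {
  cat("<go_eval> per-term evaluation of",
      length(unique(x$per_term$term_id)), "terms\n")
  print(x$summary)
  invisible(x)
}

#' Tidy and glance methods for evaluation reports
#'
#' @param x a `go_eval` report.
#' @param ... unused.
#' @return `tidy()`: the per-term tibble; `glance()`: the one-row-per-method
#'   summary.
#' @method tidy go_eval
#' @export
tidy.go_eval <- function(x, ...) x$per_term

#' @rdname tidy.go_eval
#' @method glance go_eval
#' @export
glance.go_eval <- function(x, ...) x$summary

#' Boxplots of performance by GO-term size bin
#'
#' AUROC and AUPRC distributions per size bin and method, the standard view
#' of how performance depends on how populated a term is (the AUPRC baseline
#' grows with prevalence).
#'
#' @param object a `go_eval` report.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot go_eval
#' @export
autoplot.go_eval <- function(object, ...) {
  df <- object$per_term |>
    dplyr::filter(!is.na(.data$auroc) & !is.na(.data$auprc)) |>
    tidyr::pivot_longer(c("auroc", "auprc"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size_bin, y = .data$value,
                                   fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "annotated genes per GO term", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Expected (baseline) logit of a GO term
#'
#' The log-odds a blind predictor would assign from prevalence alone:
#' `log(n_annotated / n_not_annotated)` over genes. Predictions are compared
#' against this baseline when calling gained/lost functions.
#'
#' @param n_annotated,n_not_annotated positive gene counts.
#' @return natural-log odds.
#' @export
#' @examples
#' expected_logit(10, 90) # log(1/9)
expected_logit <- function(n_annotated, n_not_annotated) {
  if (any(n_annotated <= 0) || any(n_not_annotated <= 0)) {
    stopf("expected_logit needs positive counts in both groups")
  }
  log(n_annotated / n_not_annotated)
}
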