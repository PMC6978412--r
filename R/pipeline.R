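#' Pipeline run configuration
#'
#' Collects every input and tunable for [run_pipeline()]. Inputs come either
#' in memory (`data`, the structure produced by [simulate_dataset()] or
#' [worked_example_fixture()]) or from files (`paths`, read with the
#' package's readers). Gene-level expression and domains are derived from
#' isoform-level input when not supplied.
#'
#' @param data in-memory input list with `iso_expr`, `annotations`,
#'   `iso_domains`, `map`, and optionally `gene_expr`, `gene_domains`.
#' @param paths named list of file paths (`iso_expr`, `annotations`,
#'   `iso_domains`, `map`) as an alternative to `data`.
#' @param go_min,go_max inclusive bounds for [filter_go_terms()].
#' @param dom_min,dom_max inclusive bounds for [filter_domains()].
#' @param n_test held-out gene count for the validation split.
#' @param alpha,folds,nlambda,lambda_min_ratio domain-model settings (see
#'   [fit_domain_models()]).
#' @param prior_scale,intercept_scale combination-model prior scales.
#' @param continuity Wilcoxon continuity correction flag.
#' @param lower,upper gain/loss thresholds (see [gain_loss_calls()]).
#' @param aggregation consistency aggregation (see
#'   [main_isoform_consistency()]).
#' @param seed master seed; stage seeds derive from it.
#' @param out_dir optional directory to write outputs and a manifest into.
#' @return object of class `run_config`.
#' @export
run_config <- function(data = NULL, paths = NULL, go_min = 10L,
                       go_max = 299L, dom_min = 6L, dom_max = 500L,
                       n_test = 400L, alpha = 0.5, folds = 10L,
                       nlambda = 100L, lambda_min_ratio = 1e-4,
                       prior_scale = 2.5, intercept_scale = 10,
                       continuity = FALSE, lower = -2, upper = 2,
                       aggregation = "majority", seed = 1L,
                       out_dir = NULL) {
  if (is.null(data) && is.null(paths)) stopf("supply `data` or `paths`")
  if (!is.null(paths)) {
    need <- c("iso_expr", "annotations", "iso_domains", "map")
    missing <- setdiff(need, names(paths))
    if (length(missing) > 0) {
      stopf("paths missing: %s", paste(missing, collapse = ", "))
    }
    gone <- !vapply(paths[need], file.exists, logical(1))
    if (any(gone)) {
      stopf("input file(s) not found: %s",
            paste(unlist(paths[need][gone]), collapse = ", "))
    }
  }
  structure(
    list(data = data, paths = paths, go_min = go_min, go_max = go_max,
         dom_min = dom_min, dom_max = dom_max, n_test = as.integer(n_test),
         alpha = alpha, folds = as.integer(folds),
         nlambda = as.integer(nlambda), lambda_min_ratio = lambda_min_ratio,
         prior_scale = prior_scale, intercept_scale = intercept_scale,
         continuity = continuity, lower = lower, upper = upper,
         aggregation = aggregation, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full prediction pipeline
#'
#' End-to-end flow: filter annotations and domains, split genes into
#' train/test, fit the correlation, domain and combination stages on the
#' training genes, evaluate all three on the held-out genes (evaluation
#' happens before any refit, so reported performance is always held-out),
#' refit every stage on the complete gene set, predict isoform functions,
#' and derive gain/loss calls and principal-isoform consistency. Any stage
#' failure aborts with the stage name.
#'
#' During training, the correlation reference set and the annotation counts
#' are restricted to the training genes, so no held-out label can influence
#' a held-out score; the refit uses all genes. Terms left with fewer than 2
#' annotated training genes are excluded from the training phase with a
#' warning (they still take part in the final refit).
#'
#' When `cfg$out_dir` is set, writes the evaluation report (TSV + JSON),
#' the final isoform logit matrix, changed gain/loss calls, the consistency
#' table, tidied models, and a `manifest.json` with the configuration,
#' seeds, package version and md5 checksums of every output — enough to
#' verify a byte-identical reproduction.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return object of class `isofun_run`: list with `eval` (a `go_eval`),
#'   `split`, `models` (train and full-set model objects), `isoform`
#'   (logits, z, d), `gain_loss`, `consistency`, `manifest`, `config`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  dat <- stage("load", {
    if (!is.null(cfg$data)) cfg$data else {
      iso_expr <- read_expression(cfg$paths$iso_expr)
      iso_domains <- read_domains(cfg$paths$iso_domains)
      # a pairs file only lists entities with domains: align the domain
      # matrix to the expression universe, absent rows meaning no domains
      iso_domains <- new_domain_annotation(
        expand_sparse_rows(iso_domains$pairs, rownames(iso_expr))
      )
      ann <- read_annotations(cfg$paths$annotations)
      list(
        iso_expr = iso_expr,
        annotations = ann,
        iso_domains = iso_domains,
        map = read_isoform_map(cfg$paths$map)
      )
    }
  })
  map <- isoform_map(dat$map)
  gene_expr <- dat$gene_expr %||%
    stage("aggregate", aggregate_gene_expression(dat$iso_expr, map))
  gene_dom <- dat$gene_domains %||%
    stage("gene domains", domains_to_genes(dat$iso_domains, map))

  filtered <- stage("filter", {
    ann <- filter_go_terms(dat$annotations, cfg$go_min, cfg$go_max)
    dom <- filter_domains(gene_dom, cfg$dom_min, cfg$dom_max)
    iso_dom <- new_domain_annotation(
      dat$iso_domains$pairs[, colnames(dom$pairs), drop = FALSE]
    )
    list(ann = ann, dom = dom, iso_dom = iso_dom)
  })
  ann <- filtered$ann
  if (ncol(ann$pairs) == 0) stopf("stage 'filter' failed: no terms survive")
  # align annotation and domain row spaces to the expression gene universe;
  # genes without annotations are negatives everywhere
  gene_order <- rownames(gene_expr)
  lost <- setdiff(rownames(ann$pairs)[Matrix::rowSums(ann$pairs) > 0],
                  gene_order)
  if (length(lost) > 0) {
    warnf("%d annotated gene(s) have no expression row; their annotations are dropped",
          length(lost))
  }
  ann <- new_annotation_set(expand_sparse_rows(ann$pairs, gene_order),
                            ontology = ann$term_meta$ontology)
  dom <- new_domain_annotation(expand_sparse_rows(filtered$dom$pairs,
                                                  gene_order))

  split <- stage("split",
                 split_train_test(gene_order, cfg$n_test,
                                  derive_seed(cfg$seed, 1L)))
  train <- split$train
  test <- split$test

  trained <- stage("train", {
    ann_train <- new_annotation_set(ann$pairs[train, , drop = FALSE],
                                    ontology = ann$term_meta$ontology)
    pos_train <- Matrix::colSums(ann_train$pairs)
    usable <- pos_train >= 2 & pos_train <= length(train) - 2
    if (any(!usable)) {
      warnf("%d term(s) excluded from the training phase (< 2 training positives or negatives)",
            sum(!usable))
    }
    keep <- which(usable)
    ann_train <- new_annotation_set(ann_train$pairs[, keep, drop = FALSE],
                                    ontology = ann$term_meta$ontology[keep])
    dom_train <- new_domain_annotation(dom$pairs[train, , drop = FALSE])
    corr_train <- spearman_correlation(gene_expr[train, , drop = FALSE])
    z_train <- wilcoxon_zscores(corr_train, ann_train,
                                continuity = cfg$continuity)
    corr_test <- spearman_correlation(gene_expr[test, , drop = FALSE],
                                      gene_expr[train, , drop = FALSE])
    z_test <- wilcoxon_zscores(corr_test, ann_train,
                               continuity = cfg$continuity)
    dm <- fit_domain_models(dom_train, ann_train, alpha = cfg$alpha,
                            folds = cfg$folds, seed = derive_seed(cfg$seed, 2L),
                            nlambda = cfg$nlambda,
                            lambda_min_ratio = cfg$lambda_min_ratio)
    d_train <- predict_domain_logits(dm, dom_train)
    d_test <- predict_domain_logits(
      dm, new_domain_annotation(dom$pairs[test, , drop = FALSE]))
    cm <- fit_combination(z_train, d_train, ann_train,
                          prior_scale = cfg$prior_scale,
                          intercept_scale = cfg$intercept_scale)
    combined_test <- predict_combined_logits(cm, z_test, d_test)
    list(z_test = z_test, d_test = d_test, combined_test = combined_test,
         dm = dm, cm = cm)
  })

  eval_report <- stage("evaluate", {
    per <- dplyr::bind_rows(
      dplyr::mutate(evaluate_predictions(trained$z_test, ann, entities = test),
                    method = "correlation"),
      dplyr::mutate(evaluate_predictions(trained$d_test, ann, entities = test),
                    method = "domain"),
      dplyr::mutate(evaluate_predictions(trained$combined_test, ann,
                                         entities = test),
                    method = "combination")
    )
    summarize_evaluation(per)
  })

  refit <- stage("refit", {
    corr_all <- spearman_correlation(gene_expr)
    z_all <- wilcoxon_zscores(corr_all, ann, continuity = cfg$continuity)
    dm_all <- fit_domain_models(dom, ann, alpha = cfg$alpha,
                                folds = cfg$folds,
                                seed = derive_seed(cfg$seed, 3L),
                                nlambda = cfg$nlambda,
                                lambda_min_ratio = cfg$lambda_min_ratio)
    d_all <- predict_domain_logits(dm_all, dom)
    cm_all <- fit_combination(z_all, d_all, ann,
                              prior_scale = cfg$prior_scale,
                              intercept_scale = cfg$intercept_scale)
    list(dm_all = dm_all, cm_all = cm_all)
  })

  iso <- stage("isoforms", {
    predict_isoform_functions(dat$iso_expr, gene_expr, filtered$iso_dom, ann,
                              refit$dm_all, refit$cm_all, map,
                              continuity = cfg$continuity)
  })

  gain_loss <- stage("gain/loss",
                     gain_loss_calls(iso$logits, ann, map,
                                     lower = cfg$lower, upper = cfg$upper))
  consistency <- stage("consistency",
                       main_isoform_consistency(iso$logits, ann, map,
                                                aggregation = cfg$aggregation))

  manifest <- NULL
  if (!is.null(cfg$out_dir)) {
    manifest <- stage("write", {
      write_run_outputs(cfg, eval_report, iso, gain_loss, consistency,
                        trained, refit)
    })
  }

  structure(
    list(eval = eval_report, split = split,
         models = list(domain_train = trained$dm,
                       combination_train = trained$cm,
                       domain_full = refit$dm_all,
                       combination_full = refit$cm_all),
         isoform = iso, gain_loss = gain_loss, consistency = consistency,
         manifest = manifest, config = cfg),
    class = "isofun_run"
  )
}

write_run_outputs <- function(cfg, eval_report, iso, gain_loss, consistency,
                              trained, refit) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  readr::write_tsv(eval_report$per_term, p("eval_per_term.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(summary = eval_report$summary, by_bin = eval_report$by_bin,
         by_ontology = eval_report$by_ontology,
         restricted = eval_report$restricted),
    p("eval_summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null"
  )
  write_scores(iso$logits, p("isoform_logits.tsv"), id_column = "isoform_id")
  changed <- dplyr::filter(gain_loss,
                           !is.na(.data$status) & .data$status != "unchanged")
  readr::write_tsv(changed, p("gain_loss.tsv"), progress = FALSE)
  readr::write_tsv(consistency, p("consistency.tsv"), progress = FALSE)
  readr::write_tsv(tidy(refit$dm_all), p("domain_models.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(refit$cm_all), p("combination_models.tsv"),
                   progress = FALSE)
  outputs <- c("eval_per_term.tsv", "eval_summary.json",
               "isoform_logits.tsv", "gain_loss.tsv", "consistency.tsv",
               "domain_models.tsv", "combination_models.tsv")
  manifest <- list(
    package = "isofun",
    version = as.character(utils::packageVersion("isofun")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("data", "paths", "out_dir"))],
    inputs = if (!is.null(cfg$paths)) lapply(cfg$paths, function(f)
      unname(tools::md5sum(f))) else "in-memory",
    outputs = setNames(
      lapply(outputs, function(f) unname(tools::md5sum(p(f)))), outputs)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  manifest
}

#' @export
print.isofun_run <- function(x, ...) {
  cat("<isofun_run>\n")
  print(x$eval$summary)
  cat(sprintf("isoforms scored: %d x %d terms\n",
              nrow(x$isoform$logits), ncol(x$isoform$logits)))
  if (nrow(x$consistency) > 0) {
    cat(sprintf("principal-isoform consistency: %d / %d terms fulfilled (%s)\n",
                sum(x$consistency$fulfilled), nrow(x$consistency),
                attr(x$consistency, "aggregation")))
  }
  invisible(x)
}
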