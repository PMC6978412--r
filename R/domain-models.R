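#' Fit per-term non-negative elastic-net domain models
#'
#' For every GO term, fits a penalized logistic regression predicting term
#' membership from binary protein-domain presence. Coefficients are
#' constrained non-negative so that a function can only be predicted by the
#' *presence* of domains, never their absence; the intercept is
#' unconstrained. The penalty strength lambda is chosen over a descending
#' 100-value path as the value maximizing mean out-of-fold AUROC under
#' stratified cross-validation (every fold keeps both classes). Binary
#' features are not standardized: presence/absence already shares a scale.
#'
#' Terms with fewer positive genes than `folds` have the fold count reduced
#' to the positive count (with a warning); terms with fewer than 3 positives
#' skip cross-validation and take the lambda maximizing in-sample AUROC,
#' logged in the model. A term whose domain matrix carries no variation gets
#' an intercept-only model with the closed-form null intercept
#' `log(n_pos / n_neg)`.
#'
#' @param dom gene-level [domain_annotation()] on the training genes.
#' @param ann gene-level [annotation_set()] on the same genes, same order.
#' @param alpha elastic-net mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#'   Default 0.5.
#' @param folds cross-validation folds. Default 10.
#' @param seed integer seed controlling fold assignment.
#' @param nlambda,lambda_min_ratio lambda path: `nlambda` values log-spaced
#'   down from the data-driven maximum by `lambda_min_ratio`.
#' @return object of class `domain_model_set`: per-term models with fields
#'   `term_id`, `intercept`, `coefficients` (named, non-negative, non-zero
#'   only), `lambda`, `alpha`, `cv_auroc`, `cv_trace`, `folds_used`,
#'   `intercept_only`.
#' @export
fit_domain_models <- function(dom, ann, alpha = 0.5, folds = 10L, seed = 1L,
                              nlambda = 100L, lambda_min_ratio = 1e-4) {
  stopifnot(inherits(dom, "domain_annotation"), inherits(ann, "annotation_set"))
  if (!identical(rownames(dom$pairs), rownames(ann$pairs))) {
    stopf("domain and annotation entity ids must match in order")
  }
  x <- methods::as(dom$pairs, "CsparseMatrix")
  if (ncol(x) == 1L) {
    # glmnet needs >= 2 columns; pad with an inert all-zero feature
    pad <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nrow(x), 1L),
                                dimnames = list(rownames(x), ".pad."))
    x <- cbind(x, pad)
  }
  n <- nrow(x)
  reduced <- character(0)
  models <- lapply(seq_len(ncol(ann$pairs)), function(j) {
    term <- colnames(ann$pairs)[j]
    y <- as.numeric(ann$pairs[, j])
    npos <- sum(y)
    nneg <- n - npos
    if (npos == 0) stopf("term '%s' has no positive genes", term)
    if (nneg == 0) stopf("term '%s' has no negative genes", term)
    null_intercept <- log(npos / nneg)
    if (npos < 2 || nneg < 2) {
      # a logistic fit is meaningless on a single example; keep prevalence
      warnf("term '%s' has < 2 genes in a class; intercept-only model", term)
      return(intercept_only_model(term, null_intercept, alpha))
    }
    if (ncol(x) == 0 || sum(x) == 0) {
      return(intercept_only_model(term, null_intercept, alpha))
    }
    folds_used <- folds
    if (npos < folds) {
      folds_used <- max(3L, as.integer(npos))
      reduced <<- c(reduced, term)
    }
    fit_one_domain_model(x, y, term, alpha, folds_used,
                         derive_seed(seed, j), nlambda, lambda_min_ratio,
                         null_intercept, npos)
  })
  if (length(reduced) > 0) {
    warnf("fold count reduced for %d term(s) with fewer positives than folds",
          length(reduced))
  }
  names(models) <- colnames(ann$pairs)
  structure(list(models = models, alpha = alpha, folds = folds, seed = seed),
            class = "domain_model_set")
}

intercept_only_model <- function(term, intercept, alpha) {
  list(term_id = term, intercept = intercept,
       coefficients = setNames(numeric(0), character(0)),
       lambda = Inf, alpha = alpha, cv_auroc = NA_real_,
       cv_trace = NULL, folds_used = NA_integer_, intercept_only = TRUE)
}

fit_one_domain_model <- function(x, y, term, alpha, folds, seed, nlambda,
                                 lambda_min_ratio, null_intercept, npos) {
  path_fit <- suppressWarnings(glmnet::glmnet(
    x, y, family = "binomial", alpha = alpha, lower.limits = 0,
    standardize = FALSE, nlambda = nlambda,
    lambda.min.ratio = lambda_min_ratio
  ))
  path <- path_fit$lambda
  if (npos >= 3) {
    # out-of-fold AUROC per lambda, averaged over stratified folds; the
    # fold loop is explicit so lambda is always selected on AUROC
    foldid <- stratified_folds(y, folds, seed)
    auc_folds <- vapply(seq_len(folds), function(f) {
      hold <- foldid == f
      fit_f <- suppressWarnings(glmnet::glmnet(
        x[!hold, , drop = FALSE], y[!hold], family = "binomial",
        alpha = alpha, lower.limits = 0, standardize = FALSE, lambda = path
      ))
      preds <- predict(fit_f, newx = x[hold, , drop = FALSE])
      # a refit may truncate the path; pad with its last column
      if (ncol(preds) < length(path)) {
        preds <- cbind(preds, matrix(preds[, ncol(preds)], nrow(preds),
                                     length(path) - ncol(preds)))
      }
      apply(preds, 2L, function(s) suppressWarnings(auroc(s, y[hold])))
    }, numeric(length(path)))
    cvm <- rowMeans(matrix(auc_folds, nrow = length(path)), na.rm = TRUE)
    in_sample <- FALSE
  } else {
    # too few positives to stratify folds: lambda by in-sample AUROC
    preds <- predict(path_fit, newx = x)
    cvm <- apply(preds, 2L, function(s) suppressWarnings(auroc(s, y)))
    in_sample <- TRUE
  }
  best <- which.max(cvm) # ties: first index = largest lambda on the path
  lambda <- path[best]
  cf <- as.numeric(coef(path_fit, s = lambda, exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(x))
  coefs <- cf[-1L]
  coefs <- coefs[coefs > 0]
  list(term_id = term, intercept = unname(cf[1L]), coefficients = coefs,
       lambda = lambda, alpha = alpha,
       cv_auroc = if (in_sample) NA_real_ else unname(cvm[best]),
       cv_trace = tibble::tibble(lambda = path, cv_auroc = unname(cvm),
                                 in_sample = in_sample),
       folds_used = if (in_sample) NA_integer_ else folds,
       intercept_only = length(coefs) == 0)
}

# Class-stratified fold ids: positives and negatives are each dealt around
# the folds, so AUROC is defined in every fold.
stratified_folds <- function(y, k, seed) {
  foldid <- integer(length(y))
  withr::with_seed(seed, {
    pos <- sample(which(y == 1))
    neg <- sample(which(y == 0))
  })
  foldid[pos] <- rep_len(seq_len(k), length(pos))
  foldid[neg] <- rep_len(seq_len(k), length(neg))
  foldid
}

#' Predict per-term domain logits
#'
#' Applies fitted domain models to a (gene- or isoform-level) domain matrix:
#' `logit[q, j] = intercept_j + sum_d coef_jd * presence[q, d]`. Model
#' domains absent from `dom` are treated as absent everywhere (with a
#' warning). Deterministic given the models.
#'
#' @param models a `domain_model_set` from [fit_domain_models()].
#' @param dom a [domain_annotation()] for the entities to score.
#' @return numeric logit matrix, entities x terms.
#' @export
predict_domain_logits <- function(models, dom) {
  stopifnot(inherits(models, "domain_model_set"),
            inherits(dom, "domain_annotation"))
  x <- dom$pairs
  all_coef_domains <- unique(unlist(lapply(models$models,
                                           function(m) names(m$coefficients))))
  missing <- setdiff(all_coef_domains, colnames(x))
  if (length(missing) > 0) {
    warnf("%d model domain(s) absent from input; treated as absent everywhere",
          length(missing))
  }
  beta <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(ncol(x), length(models$models)),
    dimnames = list(colnames(x), names(models$models))
  )
  for (j in seq_along(models$models)) {
    m <- models$models[[j]]
    keep <- intersect(names(m$coefficients), colnames(x))
    if (length(keep) > 0) beta[keep, j] <- m$coefficients[keep]
  }
  intercepts <- vapply(models$models, `[[`, numeric(1), "intercept")
  logits <- as.matrix(x %*% beta)
  logits <- sweep(logits, 2L, intercepts, `+`)
  dimnames(logits) <- list(rownames(x), names(models$models))
  logits
}

#' Ranked non-zero domains of a fitted model
#'
#' The domains a term's model actually uses, sorted by decreasing
#' coefficient — the interpretable output linking protein domains (including
#' domains of unknown function) to the GO terms they predict.
#'
#' @param model one element of a `domain_model_set` (or the set itself plus
#'   `term`).
#' @param top_k truncate to the `top_k` largest coefficients. Default all.
#' @param term when `model` is a `domain_model_set`, the term to extract.
#' @return tibble with `domain_id`, `coefficient`, sorted descending.
#' @export
nonzero_domains <- function(model, top_k = Inf, term = NULL) {
  if (inherits(model, "domain_model_set")) {
    stopifnot(!is.null(term))
    model <- model$models[[term]]
    if (is.null(model)) stopf("no model for term '%s'", term)
  }
  cf <- sort(model$coefficients[model$coefficients > 0], decreasing = TRUE)
  if (is.finite(top_k)) cf <- head(cf, top_k)
  tibble::tibble(domain_id = names(cf), coefficient = unname(cf))
}

#' @export
print.domain_model_set <- function(x, ...) {
  nz <- vapply(x$models, function(m) length(m$coefficients), integer(1))
  cat(sprintf(
    "<domain_model_set> %d terms (alpha = %s, %d-fold CV), median %d non-zero domains\n",
    length(x$models), format(x$alpha), x$folds, as.integer(median(nz))
  ))
  invisible(x)
}

#' Tidy a domain model set
#'
#' @param x a `domain_model_set`.
#' @param ... unused.
#' @return tibble with one row per non-zero (term, domain) coefficient plus
#'   per-term intercept rows (`domain_id = NA`).
#' @method tidy domain_model_set
#' @export
tidy.domain_model_set <- function(x, ...) {
  purrr::map(x$models, function(m) {
    tibble::tibble(
      term_id = m$term_id,
      domain_id = c(NA_character_, names(m$coefficients)),
      estimate = c(m$intercept, unname(m$coefficients))
    )
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.domain_model_set
#' @return `glance()`: one row per term with `lambda`, `cv_auroc`,
#'   `n_domains`, `folds_used`, `intercept_only`.
#' @method glance domain_model_set
#' @export
glance.domain_model_set <- function(x, ...) {
  purrr::map(x$models, function(m) {
    tibble::tibble(
      term_id = m$term_id, lambda = m$lambda, cv_auroc = m$cv_auroc,
      n_domains = length(m$coefficients), folds_used = m$folds_used,
      intercept_only = m$intercept_only
    )
  }) |> dplyr::bind_rows()
}
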