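#' Quadratic design row for the combination model
#'
#' The combination model stacks the two evidence scores on the fixed design
#' `(1, z, d, z*d, z^2, d^2)`: intercept, the correlation z-score, the
#' domain logit, their product and their squares, capturing second-order
#' interactions between the two sources.
#'
#' @param z correlation-method z-score(s), finite numeric.
#' @param d domain-method logit(s), finite numeric, same length as `z`.
#' @return numeric matrix with `length(z)` rows and columns
#'   `(Intercept), z, d, z:d, z^2, d^2`.
#' @export
#' @examples
#' build_design(2, -1)
build_design <- function(z, d) {
  if (length(z) != length(d)) stopf("z and d must have equal length")
  if (any(!is.finite(z)) || any(!is.finite(d))) {
    stopf("non-finite input to build_design")
  }
  cbind(
    "(Intercept)" = rep(1, length(z)),
    z = z, d = d, "z:d" = z * d, "z^2" = z^2, "d^2" = d^2
  )
}

combination_feature_names <- c("(Intercept)", "z", "d", "z:d", "z^2", "d^2")

#' Fit per-term combination models
#'
#' Fuses the two evidence sources per GO term with a logistic regression of
#' term membership on [build_design()], fitted by maximum a posteriori under
#' independent Cauchy priors — the standard weakly-informative recipe that
#' keeps coefficients finite even when the classes are perfectly separable
#' (the failure mode of plain maximum likelihood that motivates the choice).
#' Non-intercept features are centred and scaled by their training moments
#' before the prior applies, so `prior_scale` is on a comparable scale for
#' every feature; predictions fold the moments back in.
#'
#' Entities with a missing (degenerate) z-score are excluded from that
#' term's fit row-wise. Optimization is damped Newton on the penalized
#' deviance with step halving, so the objective is monotone; non-convergence
#' after `max_iter` iterations keeps the model with `converged = FALSE` and
#' a warning, never drops it.
#'
#' @param z z-score matrix (entities x terms) from [wilcoxon_zscores()].
#' @param d domain logit matrix (entities x terms) from
#'   [predict_domain_logits()], same dimnames.
#' @param ann gene-level [annotation_set()] on the same entities and terms.
#' @param prior_scale Cauchy scale for standardized non-intercept
#'   coefficients. Default 2.5. `Inf` gives an unpenalized fit.
#' @param intercept_scale Cauchy scale for the intercept. Default 10.
#' @param max_iter,tol optimizer budget and gradient tolerance.
#' @return object of class `combination_model_set`: per-term models with
#'   `beta` (on the standardized scale), `center`/`scale` moments,
#'   `converged`, `n_used`.
#' @export
fit_combination <- function(z, d, ann, prior_scale = 2.5,
                            intercept_scale = 10, max_iter = 100L,
                            tol = 1e-8) {
  stopifnot(is.matrix(z), is.matrix(d), inherits(ann, "annotation_set"))
  if (!identical(dimnames(z), dimnames(d))) {
    stopf("z and d must share dimnames")
  }
  if (!identical(rownames(z), rownames(ann$pairs)) ||
      !identical(colnames(z), colnames(ann$pairs))) {
    stopf("z/d and annotation set must share entity and term indices")
  }
  scales <- c(intercept_scale, rep(prior_scale, 5L))
  not_converged <- character(0)
  models <- lapply(seq_len(ncol(z)), function(j) {
    term <- colnames(z)[j]
    ok <- is.finite(z[, j]) & is.finite(d[, j])
    y <- as.numeric(ann$pairs[, j])[ok]
    if (sum(ok) < 6 || length(unique(y)) < 2) {
      return(list(term_id = term, beta = NULL, center = NULL, scale = NULL,
                  prior_scale = prior_scale, converged = FALSE,
                  n_used = sum(ok)))
    }
    X <- build_design(z[ok, j], d[ok, j])
    ctr <- c(0, colMeans(X[, -1L, drop = FALSE]))
    scl <- c(1, apply(X[, -1L, drop = FALSE], 2L, sd))
    scl[scl == 0 | !is.finite(scl)] <- 1
    Xs <- sweep(sweep(X, 2L, ctr, `-`), 2L, scl, `/`)
    Xs[, 1L] <- 1
    fit <- cauchy_map_logistic(Xs, y, scales, max_iter = max_iter, tol = tol)
    if (!fit$converged) not_converged <<- c(not_converged, term)
    list(term_id = term, beta = setNames(fit$beta, combination_feature_names),
         center = ctr, scale = scl, prior_scale = prior_scale,
         converged = fit$converged, n_used = sum(ok))
  })
  if (length(not_converged) > 0) {
    warnf("combination fit did not converge for %d term(s); kept with converged = FALSE",
          length(not_converged))
  }
  names(models) <- colnames(z)
  structure(list(models = models, prior_scale = prior_scale,
                 intercept_scale = intercept_scale,
                 feature_names = combination_feature_names),
            class = "combination_model_set")
}

# MAP logistic regression with independent Cauchy(0, scales) priors.
# Damped Newton: the Hessian uses the EM curvature of the Cauchy prior
# (its normal scale-mixture representation), directions are line-searched on
# the exact penalized objective, so it is monotone; guaranteed finite
# optimum because the prior is proper.
cauchy_map_logistic <- function(X, y, scales, max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  obj <- function(b) {
    eta <- drop(X %*% b)
    ll <- sum(ifelse(eta > 700, y * eta - eta, y * eta - log1p(exp(eta))))
    pr <- if (all(is.infinite(scales))) 0 else -sum(log1p((b / scales)^2))
    ll + pr
  }
  grad <- function(b) {
    eta <- drop(X %*% b)
    g <- drop(crossprod(X, y - plogis(eta)))
    if (!all(is.infinite(scales))) g <- g - 2 * b / (scales^2 + b^2)
    g
  }
  f <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(beta)
    if (max(abs(g)) < tol) {
      converged <- TRUE
      break
    }
    eta <- drop(X %*% beta)
    w <- plogis(eta) * (1 - plogis(eta))
    H <- crossprod(X * w, X)
    if (!all(is.infinite(scales))) {
      H <- H + diag(2 / (scales^2 + beta^2), p)
    }
    dir <- tryCatch(solve(H + diag(1e-10, p), g), error = function(e) g)
    step <- 1
    repeat {
      cand <- beta + step * dir
      fc <- obj(cand)
      if (is.finite(fc) && fc >= f - 1e-12) break
      step <- step / 2
      if (step < 1e-12) {
        cand <- beta
        fc <- f
        break
      }
    }
    if (identical(cand, beta)) break
    beta <- cand
    f <- fc
  }
  list(beta = beta, converged = converged, objective = f, iterations = it)
}

#' Predict combined logits
#'
#' Applies fitted combination models to z-score and domain-logit matrices:
#' the final entity-by-term logit of having each function. Missing z-scores
#' (degenerate terms), or terms whose model could not be fitted, propagate
#' as `NA` with a warning.
#'
#' @param models a `combination_model_set` from [fit_combination()].
#' @param z,d matrices with identical dimnames; columns must match the
#'   models' terms.
#' @return numeric logit matrix (entities x terms).
#' @export
predict_combined_logits <- function(models, z, d) {
  stopifnot(inherits(models, "combination_model_set"))
  if (!identical(dimnames(z), dimnames(d))) stopf("z and d must share dimnames")
  if (!identical(colnames(z), names(models$models))) {
    stopf("term columns do not match the fitted models")
  }
  out <- matrix(NA_real_, nrow(z), ncol(z), dimnames = dimnames(z))
  n_missing <- 0L
  for (j in seq_len(ncol(z))) {
    m <- models$models[[j]]
    ok <- is.finite(z[, j]) & is.finite(d[, j])
    n_missing <- n_missing + sum(!ok)
    if (is.null(m$beta)) {
      n_missing <- n_missing + sum(ok)
      next
    }
    if (any(ok)) {
      X <- build_design(z[ok, j], d[ok, j])
      Xs <- sweep(sweep(X, 2L, m$center, `-`), 2L, m$scale, `/`)
      Xs[, 1L] <- 1
      out[ok, j] <- drop(Xs %*% m$beta)
    }
  }
  if (n_missing > 0) {
    warnf("%d combined logit(s) missing (degenerate z-score or unfitted model)",
          n_missing)
  }
  out
}

#' @export
print.combination_model_set <- function(x, ...) {
  conv <- vapply(x$models, function(m) isTRUE(m$converged), logical(1))
  cat(sprintf(
    "<combination_model_set> %d terms, prior scale %s, %d converged\n",
    length(x$models), format(x$prior_scale), sum(conv)
  ))
  invisible(x)
}

#' Tidy a combination model set
#'
#' @param x a `combination_model_set`.
#' @param ... unused.
#' @return tibble with one row per (term, feature) coefficient on the
#'   standardized scale.
#' @method tidy combination_model_set
#' @export
tidy.combination_model_set <- function(x, ...) {
  purrr::map(x$models, function(m) {
    if (is.null(m$beta)) return(NULL)
    tibble::tibble(term_id = m$term_id, feature = names(m$beta),
                   estimate = unname(m$beta))
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.combination_model_set
#' @return `glance()`: one row per term with `converged` and `n_used`.
#' @method glance combination_model_set
#' @export
glance.combination_model_set <- function(x, ...) {
  purrr::map(x$models, function(m) {
    tibble::tibble(term_id = m$term_id, converged = isTRUE(m$converged),
                   n_used = m$n_used)
  }) |> dplyr::bind_rows()
}
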