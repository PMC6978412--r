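# Independent scalar oracles used to cross-check the vectorized
# implementations. These deliberately take the slow, obvious route.

# Spearman rho of two vectors through stats' own implementation.
oracle_spearman <- function(x, y) {
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

# Two-sample rank-sum z-score recovered from wilcox.test's tie-corrected
# normal approximation (sign from the direction of the U statistic).
oracle_wilcox_z <- function(a, b, continuity = FALSE) {
  if (length(unique(c(a, b))) == 1L) return(0)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = continuity)
  )
  u <- unname(wt$statistic)
  mu <- length(a) * length(b) / 2
  if (u == mu) return(0)
  sign(u - mu) * stats::qnorm(wt$p.value / 2, lower.tail = FALSE)
}

# AUROC by exhaustive positive-negative pair enumeration.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# AUPRC by a naive sweep over every distinct score threshold.
oracle_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(labels[called] == 1)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Random expression-like matrix with names.
random_expr <- function(n_rows, n_cols, prefix = "g") {
  m <- matrix(stats::rexp(n_rows * n_cols, rate = 0.2), n_rows,
              dimnames = list(paste0(prefix, seq_len(n_rows)),
                              paste0("s", seq_len(n_cols))))
  m
}

# Random annotation set over given entities.
random_annotation <- function(entities, n_terms, min_size = 2,
                              max_size = NULL) {
  max_size <- max_size %||% max(min_size, length(entities) %/% 2)
  pairs <- do.call(rbind, lapply(seq_len(n_terms), function(j) {
    k <- sample(seq(min_size, max_size), 1)
    data.frame(entity_id = sample(entities, k),
               term_id = sprintf("t%03d", j))
  }))
  annotation_set(pairs, entities = entities,
                 terms = sprintf("t%03d", seq_len(n_terms)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
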