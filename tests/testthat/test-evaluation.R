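test_that("train/test splits are disjoint, exhaustive, reproducible, uniform", {
  entities <- sprintf("G%02d", 1:10)
  sp <- split_train_test(entities, 3, seed = 1)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), entities)
  expect_identical(split_train_test(entities, 3, seed = 1)$test, sp$test)
  expect_error(split_train_test(entities, 0), "positive")
  expect_error(split_train_test(entities, 10), "training")

  # each entity's test frequency ~ Binomial(n_runs, 3/10) within 3 sigma
  n_runs <- 100
  freq <- table(factor(unlist(
    lapply(seq_len(n_runs), function(s) split_train_test(entities, 3, s)$test)
  ), levels = entities))
  expected <- n_runs * 3 / 10
  sigma <- sqrt(n_runs * 0.3 * 0.7)
  expect_true(all(abs(freq - expected) <= 3 * sigma))
})

test_that("auroc matches printed instances and the exhaustive pair oracle", {
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(rep(0.4, 10), rep(c(1, 0), 5)), 0.5) # all tied

  withr::with_seed(101, {
    for (rep in 1:25) {
      n <- sample(5:60, 1)
      scores <- sample(round(rnorm(n), 1)) # coarse values force ties
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                   tolerance = 1e-12)
    }
  })
  expect_warning(expect_true(is.na(auroc(1:3, c(1, 1, 1)))), "one class")
})

test_that("auprc matches printed instances and the threshold-sweep oracle", {
  expect_equal(auprc(c(0.9, 0.8, 10, 9, 8, 7, 6, 5, 4, 3) * c(1, 1, rep(0.01, 8)),
                     c(1, 1, rep(0, 8))), 1.0)
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.8333333,
               tolerance = 1e-6)

  withr::with_seed(103, {
    for (rep in 1:25) {
      n <- sample(5:60, 1)
      scores <- sample(round(rnorm(n), 1))
      labels <- rbinom(n, 1, 0.3)
      if (sum(labels) == 0) next
      expect_equal(auprc(scores, labels), oracle_auprc(scores, labels),
                   tolerance = 1e-12)
    }
  })
  expect_warning(expect_true(is.na(auprc(1:3, c(0, 0, 0)))), "positives")
})

test_that("random-score AUPRC sits at the prevalence baseline", {
  withr::with_seed(105, {
    vals <- replicate(25, {
      labels <- rbinom(500, 1, 0.1)
      auprc(rnorm(500), labels)
    })
  })
  expect_lt(abs(mean(vals) - 0.1), 0.02)
})

test_that("AUROC is invariant under strictly increasing transforms", {
  withr::with_seed(107, {
    scores <- rnorm(100)
    labels <- rbinom(100, 1, 0.3)
    a <- auroc(scores, labels)
    expect_equal(auroc(exp(scores), labels), a, tolerance = 1e-12)
    expect_equal(auroc(atan(scores) * 5 + 2, labels), a, tolerance = 1e-12)
  })
})

test_that("evaluation reports summarize medians, perfect counts and bins", {
  per <- tibble::tibble(
    term_id = c("T1", "T2", "T3"),
    ontology = c("BP", "BP", "MF"),
    n_annotated = c(20L, 21L, 115L),
    n_eval = 50L, n_pos_eval = 5L,
    auroc = c(1, 1, 0.8),
    auprc = c(1, 0.5, 0.2)
  )
  report <- summarize_evaluation(per)
  expect_s3_class(report, "go_eval")
  expect_equal(report$summary$n_perfect, 1L)
  expect_equal(report$summary$median_auroc, 1.0)
  expect_equal(report$summary$median_auprc, 0.5)
  # bin edges: 20 falls in [10,20], 21 in (20,27], 115 in (114,300]
  expect_equal(as.character(report$per_term$size_bin),
               c("[10,20]", "(20,27]", "(114,300]"))
  # restricted medians cover terms with 20 < n < 300 only
  expect_equal(report$restricted$n_terms, 2L)
  expect_equal(report$by_ontology$median_auroc[
    report$by_ontology$ontology == "MF"], 0.8)
  expect_identical(tidy(report), report$per_term)
  expect_identical(glance(report), report$summary)
  expect_s3_class(autoplot(report), "ggplot")
})

test_that("per-term evaluation agrees with direct recomputation", {
  withr::with_seed(109, {
    entities <- sprintf("G%03d", 1:80)
    ann <- random_annotation(entities, 8, min_size = 5, max_size = 30)
    scores <- matrix(rnorm(80 * 8), 80,
                     dimnames = list(entities, term_ids(ann)))
    test_set <- sample(entities, 30)
    per <- evaluate_predictions(scores, ann, entities = test_set)
    for (j in 1:8) {
      y <- as.numeric(ann$pairs[test_set, j])
      s <- scores[test_set, j]
      if (length(unique(y)) < 2) {
        expect_true(is.na(per$auroc[j]))
      } else {
        expect_equal(per$auroc[j], oracle_auroc(s, y), tolerance = 1e-12)
        expect_equal(per$auprc[j], oracle_auprc(s, y), tolerance = 1e-12)
      }
    }
    expect_identical(per$n_annotated,
                     as.integer(Matrix::colSums(ann$pairs)))
  })
})

test_that("expected logit is the log prevalence odds", {
  expect_equal(expected_logit(30, 30), 0)
  expect_equal(expected_logit(10, 90), -2.1972246, tolerance = 1e-6)
  expect_equal(expected_logit(10, 90), log(1 / 9))
  # strictly increasing in n_annotated at fixed total
  vals <- vapply(1:99, function(k) expected_logit(k, 100 - k), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(expected_logit(0, 10), "positive")
  expect_error(expected_logit(10, 0), "positive")
})
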