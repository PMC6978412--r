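# Synthetic gene universe with one domain carried by exactly the positives,
# plus noise domains.
planted_domain_data <- function(n_pos = 20, n_neg = 180, n_noise = 6,
                                seed = 2) {
  withr::with_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_pos + n_neg))
    pos <- genes[seq_len(n_pos)]
    pres <- matrix(rbinom(length(genes) * n_noise, 1, 0.15), length(genes),
                   dimnames = list(genes, sprintf("N%02d", seq_len(n_noise))))
    pairs <- rbind(
      data.frame(entity_id = pos, domain_id = "DPLANT"),
      data.frame(entity_id = rep(genes, n_noise)[pres > 0],
                 domain_id = rep(colnames(pres), each = length(genes))[pres > 0])
    )
    dom <- domain_annotation(pairs, entities = genes,
                             domains = c("DPLANT", colnames(pres)))
    ann <- annotation_set(data.frame(entity_id = pos, term_id = "T1"),
                          entities = genes)
    list(dom = dom, ann = ann, pos = pos, genes = genes)
  })
}

test_that("a perfectly informative domain is recovered with CV AUROC 1", {
  d <- planted_domain_data()
  models <- fit_domain_models(d$dom, d$ann, seed = 2)
  m <- models$models[["T1"]]
  expect_gt(m$coefficients[["DPLANT"]], 0)
  expect_equal(m$cv_auroc, 1.0)
  expect_identical(nonzero_domains(m)$domain_id[1], "DPLANT")
  # lambda selection maximizes the stored out-of-fold AUROC trace
  expect_gte(m$cv_auroc, max(m$cv_trace$cv_auroc) - 1e-12)
})

test_that("anti-correlated domains are forced to zero by non-negativity", {
  d <- planted_domain_data()
  # a domain present only in negatives
  neg <- setdiff(d$genes, d$pos)
  pairs <- data.frame(entity_id = c(d$pos, neg[1:60]),
                      domain_id = c(rep("DPLANT", length(d$pos)),
                                    rep("DANTI", 60)))
  dom <- domain_annotation(pairs, entities = d$genes,
                           domains = c("DPLANT", "DANTI"))
  models <- fit_domain_models(dom, d$ann, seed = 2)
  cf <- models$models[["T1"]]$coefficients
  expect_false("DANTI" %in% names(cf))
  expect_true(all(cf >= 0))
})

test_that("an all-zero domain matrix yields the closed-form null intercept", {
  genes <- sprintf("G%03d", 1:100)
  dom <- domain_annotation(data.frame(entity_id = character(0),
                                      domain_id = character(0)),
                           entities = genes, domains = c("D1", "D2"))
  ann <- annotation_set(data.frame(entity_id = genes[1:25], term_id = "T1"),
                        entities = genes)
  models <- fit_domain_models(dom, ann, seed = 1)
  m <- models$models[["T1"]]
  expect_true(m$intercept_only)
  logits <- predict_domain_logits(models, dom)
  expect_equal(unname(logits[, "T1"]), rep(log(25 / 75), 100),
               tolerance = 1e-6)
})

test_that("coefficients are non-negative and predictions domain-monotone", {
  withr::with_seed(31, {
    genes <- sprintf("G%03d", 1:120)
    for (rep in 1:3) {
      dom <- domain_annotation(
        data.frame(entity_id = sample(genes, 320, replace = TRUE),
                   domain_id = sample(sprintf("D%02d", 1:15), 320,
                                      replace = TRUE)),
        entities = genes, domains = sprintf("D%02d", 1:15)
      )
      ann <- random_annotation(genes, 4, min_size = 12, max_size = 40)
      models <- fit_domain_models(dom, ann, folds = 5, seed = rep)
      all_cf <- unlist(lapply(models$models, `[[`, "coefficients"))
      expect_true(all(all_cf >= 0))

      logits <- predict_domain_logits(models, dom)
      # adding any domain to an entity never decreases any logit
      for (i in sample(length(genes), 10)) {
        extra <- sample(15, 1)
        m2 <- dom$pairs
        m2[i, extra] <- 1
        logits2 <- predict_domain_logits(models, isofun:::new_domain_annotation(m2))
        expect_true(all(logits2[i, ] >= logits[i, ] - 1e-12))
        expect_equal(logits2[-i, ], logits[-i, ])
      }
    }
  })
})

test_that("prediction is deterministic and intercept-bound for empty entities", {
  d <- planted_domain_data()
  models <- fit_domain_models(d$dom, d$ann, seed = 2)
  logits <- predict_domain_logits(models, d$dom)
  # entity with no domains scores the intercept for every term
  bare <- which(Matrix::rowSums(d$dom$pairs) == 0)[1]
  expect_equal(unname(logits[bare, "T1"]),
               models$models[["T1"]]$intercept)
  # an entity sharing a training gene's domains gets the same logit
  twin <- d$dom$pairs[c(1, 1), ]
  rownames(twin) <- c("G001", "TWIN")
  expect_equal(unname(predict_domain_logits(
    models, isofun:::new_domain_annotation(twin))["TWIN", ]),
    unname(logits["G001", ]))
})

test_that("model tidiers expose coefficients and fit metadata", {
  d <- planted_domain_data()
  models <- fit_domain_models(d$dom, d$ann, seed = 2)
  td <- tidy(models)
  expect_true(all(c("term_id", "domain_id", "estimate") %in% names(td)))
  expect_true("DPLANT" %in% td$domain_id)
  gl <- glance(models)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$term_id, "T1")
  expect_false(gl$intercept_only)
})
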