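# Small end-to-end fixture: simulate genes, fit both stages on all genes,
# then score isoforms. Cached per test file.
iso_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config(n_genes = 150, n_samples = 80, n_terms = 8,
                             term_size = c(10, 20), n_domains = 30,
                             rho_signal = 0.7, iso_rate = 1.2, seed = 21)
    sim <- simulate_dataset(cfg)
    corr <- spearman_correlation(sim$gene_expr)
    z <- wilcoxon_zscores(corr, sim$annotations)
    dm <- fit_domain_models(sim$gene_domains, sim$annotations, folds = 5,
                            seed = 21)
    d <- predict_domain_logits(dm, sim$gene_domains)
    cm <- fit_combination(z, d, sim$annotations)
    iso <- suppressWarnings(predict_isoform_functions(
      sim$iso_expr, sim$gene_expr, sim$iso_domains, sim$annotations,
      dm, cm, sim$map
    ))
    cache <<- list(sim = sim, z = z, d = d, dm = dm, cm = cm, iso = iso,
                   gene_logits = predict_combined_logits(cm, z, d))
    cache
  }
})

test_that("an isoform indistinguishable from its gene inherits its logits", {
  fx <- iso_fixture()
  sim <- fx$sim
  # single-isoform genes: the isoform IS the gene (same expression, domains)
  singles <- names(which(table(sim$map$gene_id) == 1))
  iso_of <- setNames(sim$map$isoform_id, sim$map$gene_id)
  for (g in head(singles, 10)) {
    expect_equal(unname(fx$iso$logits[iso_of[[g]], ]),
                 unname(fx$gene_logits[g, ]), tolerance = 1e-9)
  }
})

test_that("losing every domain drops an isoform to the per-term intercepts", {
  fx <- iso_fixture()
  sim <- fx$sim
  iso1 <- sim$map$isoform_id[1]
  stripped <- sim$iso_domains$pairs
  stripped[iso1, ] <- 0
  d2 <- predict_domain_logits(fx$dm, isofun:::new_domain_annotation(stripped))
  intercepts <- vapply(fx$dm$models, `[[`, numeric(1), "intercept")
  expect_equal(unname(d2[iso1, ]), unname(intercepts))
})

test_that("function-losing isoforms rank below their principal sibling", {
  fx <- iso_fixture()
  sim <- fx$sim
  truth <- sim$truth
  principal_of <- setNames(sim$map$isoform_id[sim$map$principal],
                           sim$map$gene_id[sim$map$principal])
  # alternatives that decorrelated AND lost an informative domain, with a
  # faithful principal sibling, for informative terms
  losing <- truth[!truth$carries_function &
                    !truth$faithful_expression &
                    !truth$keeps_term_domains &
                    truth$term_id %in% sim$informative_terms, ]
  losing <- losing[truth$carries_function[match(
    paste(principal_of[losing$gene_id], losing$term_id),
    paste(truth$isoform_id, truth$term_id))], ]
  losing <- losing[!is.na(losing$isoform_id), ]
  expect_gt(nrow(losing), 5)
  worse <- mapply(function(i, g, t) {
    fx$iso$logits[i, t] < fx$iso$logits[principal_of[[g]], t]
  }, losing$isoform_id, losing$gene_id, losing$term_id)
  expect_gte(mean(worse), 0.95)
})

test_that("gain/loss calls follow the strict threshold rules", {
  entities <- sprintf("G%02d", 1:20)
  ann <- annotation_set(
    data.frame(entity_id = entities[1:5], term_id = "T1"),
    entities = entities
  )
  expected <- expected_logit(5, 15)
  logits <- matrix(c(expected - 5, expected + 4, expected - 3, expected + 3),
                   4, 1, dimnames = list(c("i1", "i2", "i3", "i4"), "T1"))
  map <- data.frame(isoform_id = c("i1", "i2", "i3", "i4"),
                    gene_id = c("G01", "G06", "G02", "G07"),
                    principal = FALSE)
  calls <- gain_loss_calls(logits, ann, map, lower = -3, upper = 3)
  expect_equal(calls$status[calls$isoform_id == "i1"], "lost")
  expect_equal(calls$status[calls$isoform_id == "i2"], "gained")
  # delta exactly at a threshold stays unchanged (strict inequalities)
  expect_equal(calls$status[calls$isoform_id == "i3"], "unchanged")
  expect_equal(calls$status[calls$isoform_id == "i4"], "unchanged")
  expect_equal(unique(calls$expected), expected)
  # statuses respect annotation: gains only on non-annotated genes
  expect_true(all(calls$annotated[calls$status == "lost"]))
  expect_false(any(calls$annotated[calls$status == "gained"]))
  expect_error(gain_loss_calls(logits, ann, map[1:2, ]), "mapping")
})

test_that("raising the upper threshold can only shrink the gained set", {
  fx <- iso_fixture()
  sim <- fx$sim
  calls1 <- gain_loss_calls(fx$iso$logits, sim$annotations, sim$map,
                            lower = -2, upper = 2)
  calls2 <- gain_loss_calls(fx$iso$logits, sim$annotations, sim$map,
                            lower = -2, upper = 4)
  gained1 <- with(calls1, paste(isoform_id, term_id)[!is.na(status) & status == "gained"])
  gained2 <- with(calls2, paste(isoform_id, term_id)[!is.na(status) & status == "gained"])
  expect_true(all(gained2 %in% gained1))
  # lost and gained are mutually exclusive by construction
  expect_false(any(calls1$status == "lost" & calls1$status == "gained"))
})

test_that("principal-isoform consistency aggregations follow their rules", {
  # 3 annotated genes, principal top-ranked in exactly 2 (GA and GC)
  logits <- matrix(c(5, 1, 3, 4, 6, 2), 6, 1,
                   dimnames = list(c("a1", "a2", "b1", "b2", "c1", "c2"), "T1"))
  map <- data.frame(isoform_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
                    gene_id = rep(c("GA", "GB", "GC"), each = 2),
                    principal = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  ann <- annotation_set(data.frame(entity_id = c("GA", "GB", "GC"),
                                   term_id = "T1"))
  maj <- main_isoform_consistency(logits, ann, map, "majority")
  expect_equal(maj$fraction, 2 / 3)
  expect_true(maj$fulfilled)
  expect_false(main_isoform_consistency(logits, ann, map, "all-genes")$fulfilled)
  expect_true(main_isoform_consistency(logits, ann, map, "any-gene")$fulfilled)

  # all principals on top fulfils every aggregation; ties count as success
  logits2 <- matrix(c(5, 5, 3, 1, 6, 2), 6, 1, dimnames = dimnames(logits))
  for (agg in c("majority", "any-gene", "all-genes")) {
    expect_true(main_isoform_consistency(logits2, ann, map, agg)$fulfilled)
  }
})

test_that("principal isoforms dominate on simulated data", {
  fx <- iso_fixture()
  cons <- main_isoform_consistency(fx$iso$logits, fx$sim$annotations,
                                   fx$sim$map, "majority")
  expect_gt(nrow(cons), 0)
  expect_gt(mean(cons$fulfilled), 0.9)
})
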