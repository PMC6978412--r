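expr1 <- function(...) {
  m <- rbind(...)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("spearman correlation matches closed forms and the scalar oracle", {
  x <- expr1(a = c(1, 2, 3))
  up <- expr1(y = c(10, 20, 30))
  down <- expr1(y = c(30, 20, 10))
  expect_equal(spearman_correlation(x, up)[1, 1], 1)
  expect_equal(spearman_correlation(x, down)[1, 1], -1)
  # d^2 sum 4, n = 4: 1 - 6*4/(4*15) = 0.6
  expect_equal(
    spearman_correlation(expr1(a = c(1, 2, 3, 4)),
                         expr1(b = c(2, 1, 4, 3)))[1, 1],
    0.6
  )

  withr::with_seed(5, {
    q <- random_expr(50, 20, prefix = "q")
    r <- random_expr(30, 20, prefix = "r")
    # inject ties
    q[1:5, 1:10] <- round(q[1:5, 1:10])
    rho <- spearman_correlation(q, r)
    for (i in sample(50, 12)) {
      for (j in sample(30, 6)) {
        expect_equal(rho[i, j], oracle_spearman(q[i, ], r[j, ]),
                     tolerance = 1e-12)
      }
    }
    expect_true(all(rho >= -1 & rho <= 1))
  })
})

test_that("constant rows are flagged and given zero correlation", {
  m <- expr1(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2))
  rho <- spearman_correlation(m, m)
  expect_equal(unname(rho["b", ]), c(0, 0))
  expect_identical(attr(rho, "constant_queries"), "b")
  expect_equal(unname(diag(rho)[1]), 1)
})

test_that("correlation input contracts are enforced", {
  a <- expr1(a = c(1, 2, 3))
  b <- a
  colnames(b) <- c("s1", "s2", "sX")
  expect_error(spearman_correlation(a, b), "sample")
  expect_error(spearman_correlation(a[, 1:2, drop = FALSE]), "3 samples")
})

test_that("wilcoxon z-scores reproduce the hand-ranked instance and ties rule", {
  cm <- matrix(c(0.9, 0.8, 0.1, 0.2, 0.3), 1,
               dimnames = list("q", paste0("g", 1:5)))
  ann <- annotation_set(data.frame(entity_id = c("g1", "g2"), term_id = "t"),
                        entities = paste0("g", 1:5))
  # W = 9, mu = 6, sigma = sqrt(3)
  expect_equal(wilcoxon_zscores(cm, ann)[1, 1], sqrt(3), tolerance = 1e-7)
  expect_equal(wilcoxon_zscores(cm, ann)[1, 1], 1.7320508, tolerance = 1e-6)

  tied <- matrix(rep(0.5, 5), 1, dimnames = list("q", paste0("g", 1:5)))
  expect_equal(wilcoxon_zscores(tied, ann)[1, 1], 0)
})

test_that("vectorized z equals the scalar oracle, with and without exclusion", {
  withr::with_seed(13, {
    ref <- random_expr(40, 15, prefix = "g")
    queries <- random_expr(30, 15, prefix = "g") # ids overlap the reference
    rho <- spearman_correlation(queries, ref)
    ann <- random_annotation(rownames(ref), 10, min_size = 3, max_size = 20)
    z <- wilcoxon_zscores(rho, ann)
    for (qi in sample(30, 10)) {
      q <- rownames(queries)[qi]
      for (tj in sample(10, 5)) {
        members <- rownames(ref)[ann$pairs[, tj] != 0]
        keep <- setdiff(rownames(ref), q) # self-exclusion
        a <- rho[qi, intersect(keep, members)]
        b <- rho[qi, setdiff(keep, members)]
        expect_equal(z[qi, tj], oracle_wilcox_z(a, b), tolerance = 1e-9,
                     label = sprintf("z[%s, %s]", q, colnames(z)[tj]))
      }
    }
  })
})

test_that("host-gene exclusion for isoform queries matches the scalar route", {
  withr::with_seed(14, {
    ref <- random_expr(25, 12, prefix = "g")
    iso <- random_expr(10, 12, prefix = "i")
    host <- setNames(sample(rownames(ref), 10), rownames(iso))
    rho <- spearman_correlation(iso, ref)
    ann <- random_annotation(rownames(ref), 6, min_size = 3, max_size = 12)
    z <- wilcoxon_zscores(rho, ann, query_genes = host)
    for (qi in 1:10) {
      for (tj in 1:6) {
        members <- rownames(ref)[ann$pairs[, tj] != 0]
        keep <- setdiff(rownames(ref), host[qi])
        a <- rho[qi, intersect(keep, members)]
        b <- rho[qi, setdiff(keep, members)]
        expected <- if (length(a) < 2 || length(b) < 2) NA_real_
                    else oracle_wilcox_z(a, b)
        expect_equal(z[qi, tj], expected, tolerance = 1e-9)
      }
    }
  })
})

test_that("rank-sum z is antisymmetric, shift-monotone and rank-invariant", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- sample(10:40, 1)
      rho <- matrix(runif(n, -1, 1), 1, dimnames = list("q", paste0("g", 1:n)))
      k <- sample(3:(n - 3), 1)
      members <- paste0("g", sample(n, k))
      ann <- annotation_set(data.frame(entity_id = members, term_id = "t"),
                            entities = paste0("g", 1:n))
      flipped <- annotation_set(
        data.frame(entity_id = setdiff(paste0("g", 1:n), members),
                   term_id = "t"),
        entities = paste0("g", 1:n)
      )
      z0 <- wilcoxon_zscores(rho, ann, exclude_self = FALSE)[1, 1]
      expect_equal(wilcoxon_zscores(rho, flipped, exclude_self = FALSE)[1, 1],
                   -z0, tolerance = 1e-12)
      # shifting annotated correlations up never decreases z
      rho_up <- rho
      rho_up[1, members] <- rho_up[1, members] + 0.4
      expect_gte(wilcoxon_zscores(rho_up, ann, exclude_self = FALSE)[1, 1],
                 z0 - 1e-12)
      # strictly increasing transform leaves the rank statistic unchanged
      rho_tr <- tanh(2 * rho) + 3
      expect_equal(wilcoxon_zscores(rho_tr, ann, exclude_self = FALSE)[1, 1],
                   z0, tolerance = 1e-12)
    }
  })
})

test_that("terms without enough genes in a group are missing with a warning", {
  cm <- matrix(runif(5), 1, dimnames = list("q", paste0("g", 1:5)))
  ann <- annotation_set(data.frame(entity_id = "g1", term_id = "t"),
                        entities = paste0("g", 1:5))
  expect_warning(z <- wilcoxon_zscores(cm, ann), "degenerate")
  expect_true(is.na(z[1, 1]))
  expect_identical(attr(z, "n_degenerate"), 1L)
})
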