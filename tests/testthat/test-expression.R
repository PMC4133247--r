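test_that("RPKM implements reads * 1e9 / (length * total)", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(5, 500, 2e6), 5)
  expect_error(rpkm(5, 0, 1e6), "length")
  expect_error(rpkm(5, 500, 0), "total")
  expect_error(rpkm(-1, 500, 1e6), "negative")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03, 0.04)),
               c(0.004, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(1), 1)
  p <- sort(runif(50))
  q <- bh_adjust(p)
  expect_true(all(q >= p))          # adjustment never decreases a p-value
  expect_true(!is.unsorted(q))      # monotone on sorted input
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calling requires both the FDR and the fold-change rule", {
  counts <- tibble::tibble(
    gene_id = c("flat", "strong", "weak_sig", "zero_one"),
    length_bp = 1000L,
    reads_1 = c(500L, 500L, 4000L, 0L),
    reads_2 = c(500L, 3000L, 5000L, 50L)
  )
  res <- tidy(deg_call(counts, total_1 = 1e5, total_2 = 1e5))
  expect_false(res$deg[res$gene_id == "flat"])     # fold 1
  expect_true(res$deg[res$gene_id == "strong"])    # fold 6, p tiny
  # significant count difference but fold 1.25: not a DEG
  w <- res[res$gene_id == "weak_sig", ]
  expect_lt(w$p_adjusted, 0.01)
  expect_false(w$deg)
  # 0 -> 50 reads: infinite fold passes with a small p
  z <- res[res$gene_id == "zero_one", ]
  expect_equal(z$fold_change, Inf)
  expect_true(z$deg)
  # per-gene p agrees with the reference Fisher implementation on the 2x2
  expect_equal(res$p_value[res$gene_id == "strong"],
               stats::fisher.test(matrix(c(500, 1e5 - 500, 3000, 1e5 - 3000),
                                         2, byrow = TRUE))$p.value,
               tolerance = 1e-6)
})

test_that("swapping libraries flags the same genes with reciprocal folds", {
  set.seed(2020)
  counts <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:30),
    length_bp = sample(300:3000, 30),
    reads_1 = rnbinom(30, mu = 200, size = 5),
    reads_2 = rnbinom(30, mu = 200, size = 5)
  )
  counts$reads_2[1:3] <- counts$reads_1[1:3] * 8L   # planted DEGs
  a <- tidy(deg_call(counts, total_1 = 1e5, total_2 = 1e5))
  swapped <- dplyr::rename(counts, reads_1 = "reads_2", reads_2 = "reads_1")
  b <- tidy(deg_call(swapped, total_1 = 1e5, total_2 = 1e5))
  expect_equal(a$deg, b$deg)
  expect_equal(a$fold_change, 1 / b$fold_change, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("hypergeometric enrichment matches direct enumeration", {
  # draw 2 of 10, 5 annotated, both annotated: C(5,2)/C(10,2) = 10/45
  e <- hypergeom_enrich(2, 2, 10, 5, n_terms = 1)
  expect_equal(e$p_value, 10 / 45, tolerance = 1e-12)
  # zero annotated in the draw: upper tail P(X >= 0) = 1
  expect_equal(hypergeom_enrich(3, 0, 10, 5)$p_value, 1)
  # Bonferroni caps at 1
  expect_equal(hypergeom_enrich(2, 2, 10, 5, n_terms = 100)$p_adjusted, 1)
  expect_error(hypergeom_enrich(5, 6, 10, 8), "inconsistent")

  # exhaustive check against enumeration for a small population
  pop <- 20; ann <- 7
  for (drawn in 1:10) {
    for (x in 0:min(drawn, ann)) {
      direct <- sum(choose(ann, x:min(drawn, ann)) *
                      choose(pop - ann, drawn - x:min(drawn, ann))) /
        choose(pop, drawn)
      expect_equal(hypergeom_enrich(drawn, x, pop, ann)$p_value, direct,
                   tolerance = 1e-12, info = paste(drawn, x))
    }
  }
})

test_that("ddCT arithmetic matches the Livak method", {
  expect_equal(ddct(20, 18, 22, 20), 1)       # ddCT = 0
  expect_equal(ddct(20, 18, 22, 18), 4)       # ddCT = -2
  expect_equal(ddct(21, 18, 20, 18), 0.5)     # one extra cycle in treated
  expect_error(ddct(-1, 18, 20, 18), "positive")
})

test_that("efficiency coefficient and normalization invert each other", {
  expect_equal(allele_efficiency_coeff(20, 20), 1)
  expect_equal(allele_efficiency_coeff(21, 20), 0.5)
  # the published coefficient of 1.11 corresponds to dCT = -log2(1.11)
  expect_equal(allele_efficiency_coeff(20 - log2(1.11), 20), 1.11)
  # raw ratio equal to the coefficient means no true imbalance
  expect_equal(normalized_allele_ratio(20 - log2(1.11), 20, 1.11), 1)
  expect_equal(4.85 / 1.11, normalized_allele_ratio(20 - log2(4.85), 20, 1.11),
               tolerance = 1e-12)
  expect_error(normalized_allele_ratio(20, 20, 0), "positive")
})

test_that("the qPCR simulator round-trips through the full analysis", {
  q <- sim_qpcr(allele_ratio = 4, efficiency_coeff = 1.11,
                expression_fold = 3.5, noise_sd = 0, seed = 2)
  ratio <- allele_expression_ratio(q)
  expect_equal(unique(round(ratio$coefficient, 12)), 1.11)
  expect_equal(ratio$normalized_ratio, rep(4, nrow(ratio)))
  expect_equal(expression_fold(q), 3.5)

  # with noise the recovery is unbiased within sampling error
  qn <- sim_qpcr(allele_ratio = 4, efficiency_coeff = 1.11,
                 expression_fold = 3.5, noise_sd = 0.05, n_replicates = 10,
                 seed = 3)
  rn <- allele_expression_ratio(qn)
  expect_equal(rn$normalized_ratio, rep(4, nrow(rn)), tolerance = 0.15)
})
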