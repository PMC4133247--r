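test_that("sim_reference is deterministic, bounded and validates input", {
  r1 <- sim_reference(1, c(100, 100), seed = 1)
  r2 <- sim_reference(1, c(100, 100), seed = 1)
  expect_identical(r1, r2)
  expect_equal(r1$length, 100)

  expect_error(sim_reference(0, c(100, 100)), ">= 1")
  expect_error(sim_reference(5, c(80, 200)), ">= 100")

  big <- sim_reference(200, c(200, 2000), seed = 7)
  expect_equal(nrow(big), 200)
  expect_true(all(big$length >= 200 & big$length <= 2000))
  expect_true(all(grepl("^[ACGT]+$", big$sequence)))
})

test_that("sim_pooled_calls is deterministic and honours zero rates", {
  ref <- sim_reference(30, c(300, 800), seed = 2)
  s1 <- sim_pooled_calls(ref, seed = 5)
  s2 <- sim_pooled_calls(ref, seed = 5)
  expect_identical(s1$north, s2$north)
  expect_identical(s1$south, s2$south)
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))

  empty <- sim_pooled_calls(ref, category_rates = c(inter = 0, shared = 0,
                                                    north = 0, south = 0),
                            n_density_clusters = 0, seed = 5)
  expect_equal(nrow(empty$north), 0)
  expect_equal(nrow(empty$south), 0)
})

test_that("planted genotypes follow their category pattern exactly", {
  ref <- sim_reference(60, c(300, 1200), seed = 4)
  sim <- sim_pooled_calls(ref, category_rates = c(inter = 25, shared = 25,
                                                  north = 25, south = 25),
                          violate_frac = c(score = 0, depth = 0, minor = 0),
                          n_density_clusters = 0, seed = 4)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    ngt <- if (is.na(tr$north_gt[i])) paste0(tr$ref[i], tr$ref[i]) else tr$north_gt[i]
    sgt <- if (is.na(tr$south_gt[i])) paste0(tr$ref[i], tr$ref[i]) else tr$south_gt[i]
    expect_equal(classify_oracle(tr$ref[i], ngt, sgt), tr$category[i])
  }
  # north/south call tables contain exactly the sites whose pool genotype
  # differs from the reference
  expect_setequal(heatsnp::snp_unigene(paste0(sim$north$unigene_id, "-",
                                              sim$north$pos)),
                  unique(tr$unigene_id[!is.na(tr$north_gt)]))
  expect_equal(nrow(sim$north), sum(!is.na(tr$north_gt)))
  expect_equal(nrow(sim$south), sum(!is.na(tr$south_gt)))
})

test_that("forced filter violators are rejected downstream by their rule", {
  ref <- sim_reference(80, c(400, 1500), seed = 8)
  sim <- sim_pooled_calls(ref, category_rates = c(inter = 10, shared = 10,
                                                  north = 60, south = 10),
                          violate_frac = c(score = 0.1, depth = 0.1,
                                           minor = 0.1),
                          n_density_clusters = 2, seed = 8)
  res <- filter_variants(sim$north)
  ledger <- res$rejected
  viol <- sim$truth[sim$truth$forced_violation != "none", ]
  rule_map <- c(score = "genotype_score", depth = "depth",
                minor = "minor_depth", density = "density")
  for (i in seq_len(nrow(viol))) {
    hit <- ledger[ledger$snp_id == viol$snp_id[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$rule, unname(rule_map[viol$forced_violation[i]]))
  }
})

test_that("pooled frequencies are recovered within 3 binomial SE at depth >= 30", {
  ref <- sim_reference(100, c(400, 1500), seed = 12)
  sim <- sim_pooled_calls(ref, category_rates = c(inter = 0, shared = 150,
                                                  north = 0, south = 0),
                          shared_diff_frac = 0, depth_mean = 60,
                          violate_frac = c(score = 0, depth = 0, minor = 0),
                          n_density_clusters = 0, seed = 12)
  calls <- sim$north[sim$north$depth >= 30, ]
  tr <- sim$truth
  ad <- as.matrix(calls[paste0("depth_", c("A", "C", "G", "T"))])
  total <- rowSums(ad)
  ids <- paste0(calls$unigene_id, "-", calls$pos)
  focal <- tr$focal[match(ids, tr$snp_id)]
  f_true <- tr$f_north[match(ids, tr$snp_id)]
  f_hat <- ad[cbind(seq_len(nrow(calls)), match(focal, c("A", "C", "G", "T")))] /
    total
  se <- sqrt(f_true * (1 - f_true) / total)
  expect_true(all(abs(f_hat - f_true) <= 3 * se + 1e-12))
})

test_that("sim_cohort validates input and plants the effect honestly", {
  expect_error(sim_cohort(3), "at least 4")
  expect_error(sim_cohort(10, odds_ratio = 0), "positive")
  expect_error(sim_cohort(10, odds_ratio = -2), "positive")

  co <- sim_cohort(60, n_snps = 8, odds_ratio = 6, seed = 15)
  expect_equal(dim(co$genotypes), c(60L, 8L))
  expect_equal(nrow(co$phenotypes), 60)
  expect_true(all(co$phenotypes$degree_hours >= 0))
  expect_identical(sim_cohort(60, n_snps = 8, odds_ratio = 6, seed = 15)$phenotypes,
                   co$phenotypes)
  # risk-allele carriers die earlier on average under a strong effect
  eff <- co$truth$effect_snp
  g <- co$genotypes$calls[[eff]]
  carrier <- grepl(co$truth$risk_allele, g)
  expect_lt(mean(co$phenotypes$death_time[carrier]),
            mean(co$phenotypes$death_time[!carrier]))
})

test_that("sim_qpcr validates and encodes its parameters exactly at zero noise", {
  expect_error(sim_qpcr(allele_ratio = 0), "positive")
  expect_error(sim_qpcr(allele_ratio = -1), "positive")
  expect_error(sim_qpcr(noise_sd = -0.1), "non-negative")

  # equal efficiency, balanced alleles: gDNA and cDNA allele CTs coincide
  q <- sim_qpcr(allele_ratio = 1, efficiency_coeff = 1, noise_sd = 0, seed = 1)
  het <- q[q$primer %in% c("allele1", "allele2"), ]
  wide <- tidyr::pivot_wider(het, names_from = "primer", values_from = "ct")
  expect_equal(wide$allele1, wide$allele2)

  q2 <- sim_qpcr(allele_ratio = 4, noise_sd = 0, seed = 1)
  ratio <- allele_expression_ratio(q2)
  expect_equal(ratio$normalized_ratio, rep(4, nrow(ratio)))
})
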