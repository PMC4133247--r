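test_that("exact HWE test reproduces hand-enumerated cases", {
  # 2 individuals, both het: support {0, 2} with probs 1/3, 2/3 -> p = 1
  expect_equal(hwe_exact(0, 2, 0), 1)
  # extreme heterozygote deficit
  expect_lt(hwe_exact(50, 0, 50), 1e-10)
  # balanced genotypes sit at the distribution's mode
  expect_gte(hwe_exact(25, 50, 25), 0.5)
  # monomorphic SNPs are trivially in equilibrium
  expect_equal(hwe_exact(30, 0, 0), 1)
  expect_error(hwe_exact(0, 0, 0), "all genotype counts zero")
  expect_error(hwe_exact(-1, 2, 0), "non-negative")
})

test_that("exact HWE matches the enumeration oracle for all n <= 25", {
  for (n_aa in 0:25) {
    for (n_ab in 0:(25 - n_aa)) {
      for (n_bb in 0:(25 - n_aa - n_ab)) {
        if (n_aa + n_ab + n_bb == 0) next
        expect_equal(hwe_exact(n_aa, n_ab, n_bb),
                     hwe_oracle(n_aa, n_ab, n_bb), tolerance = 1e-12,
                     info = paste(n_aa, n_ab, n_bb))
      }
    }
  }
})

test_that("Fisher allelic test reproduces known tables", {
  expect_equal(fisher_allelic(5, 5, 5, 5)$p_value, 1)
  # direct hypergeometric enumeration: N = 20, margins 10/10
  expect_equal(fisher_allelic(1, 9, 9, 1)$p_value, 202 / 184756,
               tolerance = 1e-12)
  expect_equal(fisher_allelic(32, 62, 10, 84)$p_value, 1.847e-4,
               tolerance = 1e-3)
  # odds ratio conventions
  expect_equal(fisher_allelic(2, 3, 4, 5)$odds_ratio, 10 / 12)
  expect_equal(fisher_allelic(2, 0, 4, 5)$odds_ratio, Inf)
  expect_error(fisher_allelic(0, 0, 4, 5), "margins must be positive")
  expect_error(fisher_allelic(1.5, 2, 3, 4), "integers")
})

test_that("Fisher test is invariant under simultaneous row and column swap", {
  set.seed(1010)
  for (rep in 1:100) {
    t4 <- rmultinom(1, sample(10:120, 1), runif(4, 0.05, 1))[, 1]
    if (t4[1] + t4[2] == 0 || t4[3] + t4[4] == 0) next
    p1 <- fisher_allelic(t4[1], t4[2], t4[3], t4[4])$p_value
    expect_equal(fisher_allelic(t4[3], t4[4], t4[1], t4[2])$p_value, p1,
                 tolerance = 1e-12)
    expect_equal(fisher_allelic(t4[2], t4[1], t4[4], t4[3])$p_value, p1,
                 tolerance = 1e-12)
  }
})

test_that("QC removes individuals and SNPs at the strict thresholds", {
  # 20 individuals x 30 SNPs. Individual i20 misses 3/30 = 0.1 calls
  # (exactly at the strict boundary -> removed); i19 misses 2/30 and is
  # kept. SNP s29 is missing for 10 individuals (10/19 >= 0.5 among the
  # survivors -> removed); s30 has no heterozygotes at all (HWE p <<
  # 0.001 -> removed). The other 28 SNPs sit in perfect HWE proportions.
  base_gt <- rep(c("AA", "AC", "AC", "CC"), 5)
  calls <- tibble::tibble(individual_id = sprintf("i%02d", 1:20))
  for (k in 1:28) calls[[sprintf("s%02d", k)]] <- base_gt
  calls$s29 <- c(rep(NA_character_, 10), base_gt[11:20])
  calls$s30 <- rep(c("AA", "TT"), 10)
  calls$s01[20] <- NA
  calls$s02[20] <- NA
  calls$s03[20] <- NA
  calls$s04[19] <- NA
  calls$s05[19] <- NA
  snps <- tibble::tibble(snp_id = sprintf("s%02d", 1:30),
                         a1 = c(rep("A", 29), "A"),
                         a2 = c(rep("C", 29), "T"))
  gm <- genotype_matrix(calls, snps)
  qc <- qc_genotypes(gm)
  expect_false("i20" %in% qc$matrix$calls$individual_id)
  expect_true("i19" %in% qc$matrix$calls$individual_id)
  expect_setequal(qc$matrix$snps$snp_id, sprintf("s%02d", 1:28))
  led <- qc$removed
  expect_equal(led$id[led$type == "individual"], "i20")
  expect_equal(led$reason[led$id == "s29"], "missing_rate")
  expect_equal(led$reason[led$id == "s30"], "hwe")
  # the HWE threshold is strict: p must exceed 0.001 to survive
  expect_lt(hwe_exact(10, 0, 10), 0.001)
})

test_that("QC ledger plus surviving matrix account for the whole input", {
  co <- sim_cohort(80, n_snps = 12, missing_rate = 0.15, seed = 33)
  qc <- qc_genotypes(co$genotypes)
  ind_removed <- qc$removed$id[qc$removed$type == "individual"]
  snp_removed <- qc$removed$id[qc$removed$type == "snp"]
  expect_setequal(c(qc$matrix$calls$individual_id, ind_removed),
                  co$genotypes$calls$individual_id)
  expect_setequal(c(qc$matrix$snps$snp_id, snp_removed),
                  co$genotypes$snps$snp_id)
})

test_that("count reconstruction inverts printed frequencies", {
  r <- reconstruct_counts(0.3404, 4)
  expect_equal(c(r$k, r$n), c(32, 94))
  expect_false(r$ambiguous)
  r <- reconstruct_counts(0.1064, 4)
  expect_equal(c(r$k, r$n), c(10, 94))
  # 3-decimal printing is less constrained: largest-n rule still applies
  r <- reconstruct_counts(0.106, 3)
  expect_equal(c(r$k, r$n), c(10, 94))
  # 0.5 matches many (k, n): flagged ambiguous, largest n returned
  r <- reconstruct_counts(0.5, 4)
  expect_true(r$ambiguous)
  expect_equal(c(r$k, r$n), c(48, 96))
  # 0.0001 cannot be a 4-decimal rounding of any k/n with even n <= 96
  expect_error(reconstruct_counts(0.0001, 4), "no \\(k, n\\)")
  expect_error(reconstruct_counts(1.2, 4), "outside")
  expect_error(reconstruct_counts(0.5, 4, n_min = 47), "even")
})

test_that("run_association tallies alleles, skips monomorphic, sorts by p", {
  calls <- tibble::tibble(
    individual_id = sprintf("i%02d", 1:8),
    s1 = c("CC", "CC", "CT", "CT", "TT", "TT", "TT", "TT"),
    s2 = rep("AA", 8),
    s3 = c("AG", "GG", NA, "AG", "AA", "AA", "AG", "AA")
  )
  snps <- tibble::tibble(snp_id = c("s1", "s2", "s3"),
                         a1 = c("C", "A", "A"), a2 = c("T", "A", "G"))
  gm <- genotype_matrix(calls, snps)
  res <- run_association(gm, sprintf("i%02d", 1:4), sprintf("i%02d", 5:8))
  tidy_res <- tidy(res)
  expect_equal(nrow(tidy_res), 2)
  expect_equal(res$skipped$snp_id, "s2")
  # s1: cases 6 C + 2 T, controls 0 C + 8 T
  s1 <- tidy_res[tidy_res$snp_id == "s1", ]
  expect_equal(c(s1$a, s1$b, s1$c, s1$d), c(6, 2, 0, 8))
  expect_equal(s1$freq_case, 0.75)
  expect_equal(s1$p_value, fisher_oracle(6, 2, 0, 8), tolerance = 1e-12)
  # missing genotypes contribute no alleles
  s3 <- tidy_res[tidy_res$snp_id == "s3", ]
  expect_equal(s3$n_case, 6)
  expect_true(!is.unsorted(tidy_res$p_value))
  expect_error(run_association(gm, c("i01", "i02"), c("i02", "i03")),
               "overlap")
  expect_error(run_association(gm, "i01", "nope"), "unknown individual")
  g <- glance(res)
  expect_equal(g$n_tested, 2)
  expect_equal(g$top_snp, tidy_res$snp_id[1])
})

test_that("association plot builds without error", {
  co <- sim_cohort(40, n_snps = 6, odds_ratio = 3, seed = 41)
  ex <- select_extremes(co$phenotypes, 15)
  res <- run_association(co$genotypes, ex$susceptible$individual_id,
                         ex$resistant$individual_id)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
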