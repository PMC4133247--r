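test_that("IUPAC coding follows the standard table and round-trips", {
  expect_equal(iupac_code("TG"), "K")
  expect_equal(iupac_code(c("A", "C")), "M")
  expect_equal(iupac_code("AA"), "A")
  expect_equal(iupac_code(c("AG", "CT", "GG")), c("R", "Y", "G"))
  expect_equal(iupac_decode("M"), c("A", "C"))
  expect_equal(iupac_decode("A"), c("A", "A"))
  expect_error(iupac_code("AX"), "non-ACGT")
  expect_error(iupac_decode("Z"), "unknown code")
  # round trip over every genotype
  for (g in all_genotypes()) {
    expect_equal(paste(iupac_decode(iupac_code(g)), collapse = ""), g)
  }
})

test_that("classify_site reproduces the canonical category examples", {
  expect_equal(classify_site("A", "GG", "AA")$category, "north_specific")
  expect_equal(classify_site("A", "GG", "TT")$category, "inter_subspecific")
  expect_equal(classify_site("A", "AG", "AG")$category, "shared_same_het")
  expect_equal(classify_site("A", "AG", "AC")$category, "shared_diff_het")
  expect_true(is.na(classify_site("A", "AA", "AA")$category))
  # absence = hom-reference by default
  expect_equal(classify_site("A", north = "AG")$category, "north_specific")
  expect_equal(classify_site("A", south = "CC")$category, "south_specific")
  expect_error(classify_site("A"), "both pools absent")
  expect_error(classify_site("X", "AA", "AA"), "non-ACGT")
  # absent-as-unknown mode skips one-pool sites
  skip <- classify_site("A", north = "AG", absent_as_ref = FALSE)
  expect_true(is.na(skip$category))
  expect_equal(skip$note, "absent_pool")
})

test_that("classify_site matches the rule-by-rule oracle on every combination", {
  gts <- all_genotypes()
  for (ref in c("A", "C", "G", "T")) {
    for (ngt in c(gts, NA)) {
      for (sgt in c(gts, NA)) {
        if (is.na(ngt) && is.na(sgt)) next
        got <- classify_site(ref, ngt, sgt)$category
        n_res <- if (is.na(ngt)) paste0(ref, ref) else ngt
        s_res <- if (is.na(sgt)) paste0(ref, ref) else sgt
        expect_equal(got, classify_oracle(ref, n_res, s_res),
                     info = paste(ref, ngt, sgt))
      }
    }
  }
})

test_that("classification is symmetric under pool swap", {
  gts <- all_genotypes()
  swap_map <- c(north_specific = "south_specific",
                south_specific = "north_specific",
                inter_subspecific = "inter_subspecific",
                shared_same_het = "shared_same_het",
                shared_diff_het = "shared_diff_het")
  for (ref in c("A", "G")) {
    for (ngt in gts) {
      for (sgt in gts) {
        a <- classify_site(ref, ngt, sgt)$category
        b <- classify_site(ref, sgt, ngt)$category
        if (is.na(a)) expect_true(is.na(b)) else
          expect_equal(b, unname(swap_map[a]))
      }
    }
  }
})

test_that("classify_snps recovers planted categories exactly at zero noise", {
  ref <- sim_reference(50, c(300, 1200), seed = 51)
  sim <- sim_pooled_calls(ref, category_rates = c(inter = 10, shared = 10,
                                                  north = 10, south = 10),
                          shared_diff_frac = 0.5,
                          violate_frac = c(score = 0, depth = 0, minor = 0),
                          n_density_clusters = 0, seed = 51)
  cl <- classify_snps(sim$north, sim$south)
  joined <- dplyr::inner_join(cl, sim$truth, by = "snp_id",
                              suffix = c("_got", "_true"))
  expect_equal(nrow(joined), nrow(sim$truth))
  expect_equal(joined$category_got, joined$category_true)
  counts <- category_counts(cl)
  true_counts <- as.data.frame(table(sim$truth$category))
  for (i in seq_len(nrow(true_counts))) {
    expect_equal(counts$n[counts$category == true_counts$Var1[i]],
                 true_counts$Freq[i])
  }
  # four-way reporting aggregates the two shared classes
  fw <- category_counts(cl, four_way = TRUE)
  expect_equal(fw$n[fw$category == "shared"], 10L)
  expect_equal(sum(fw$n), sum(counts$n))
})

test_that("classify_snps handles empty and one-sided inputs", {
  empty <- sim_pooled_calls(sim_reference(5, c(200, 300), seed = 1),
                            category_rates = c(inter = 0, shared = 0,
                                               north = 0, south = 0),
                            n_density_clusters = 0, seed = 1)
  cl <- classify_snps(empty$north, empty$south)
  expect_equal(nrow(cl), 0)

  sim <- sim_pooled_calls(sim_reference(20, c(300, 800), seed = 9),
                          category_rates = c(inter = 0, shared = 0,
                                             north = 15, south = 0),
                          violate_frac = c(score = 0, depth = 0, minor = 0),
                          n_density_clusters = 0, seed = 9)
  cl <- classify_snps(sim$north, sim$south)
  expect_true(all(cl$category == "north_specific"))
})

test_that("conflicting reference alleles across pools are an error", {
  n <- tibble::tibble(unigene_id = "u1", pos = 10L, ref = "A",
                      genotype = "AG", score = 60, depth = 30L,
                      depth_A = 15L, depth_C = 0L, depth_G = 15L, depth_T = 0L)
  s <- dplyr::mutate(n, ref = "C", genotype = "CG")
  expect_error(classify_snps(n, s), "conflicting reference allele at u1-10")
})

test_that("category partition: classified sites sum over categories", {
  sim <- sim_pooled_calls(sim_reference(40, c(300, 900), seed = 77), seed = 77)
  cl <- classify_snps(sim$north, sim$south)
  expect_equal(sum(category_counts(cl)$n), sum(!is.na(cl$category)))
})
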