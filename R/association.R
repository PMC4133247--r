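# Allelic case-control association: genotype-matrix QC (missingness and
# exact Hardy-Weinberg), two-sided Fisher exact allelic tests, and a
# count-reconstruction utility for validating against published allele
# frequency tables.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test of Hardy-Weinberg genotype
#' proportions: conditional on the observed allele counts, the p-value
#' is the sum of probabilities of every heterozygote count whose point
#' probability does not exceed the observed one (no mid-p correction).
#' The conditional distribution of the heterozygote count h given n
#' individuals and n_A copies of allele A is
#' `P(h) = n! / (n_AA! h! n_aa!) * 2^h * n_A! n_a! / (2n)!`
#' with `n_AA = (n_A - h) / 2`.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (non-negative integers,
#'   sum >= 1).
#' @return The exact p-value in `(0, 1]`.
#' @examples
#' hwe_exact(0, 2, 0)   # 1
#' hwe_exact(50, 0, 50) # ~ 0: extreme heterozygote deficit
#' @export
hwe_exact <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("hwe_exact: genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) abort("hwe_exact: all genotype counts zero")
  n_a <- 2 * n_hom1 + n_het
  n_b <- 2 * n_hom2 + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)           # monomorphic: single support point
  h_vals <- seq(rare %% 2, rare, by = 2)
  log_p <- lgamma(n + 1) - lgamma((n_a - h_vals) / 2 + 1) -
    lgamma(h_vals + 1) - lgamma((n_b - h_vals) / 2 + 1) +
    h_vals * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  p_vals <- exp(log_p - max(log_p))
  p_vals <- p_vals / sum(p_vals)
  p_obs <- p_vals[match(n_het, h_vals)]
  if (is.na(p_obs)) {
    abort("hwe_exact: heterozygote count inconsistent with allele counts")
  }
  min(1, sum(p_vals[p_vals <= p_obs * (1 + 1e-7)]))
}

#' Two-sided Fisher exact test on a 2x2 allele table
#'
#' Tests equality of allele frequencies between two groups from the
#' table `[[a, b], [c, d]]` (rows = groups, columns = alleles). The
#' two-sided p-value is the sum over all tables with the observed
#' margins whose point hypergeometric probability is less than or equal
#' to the observed table's (the convention of the usual association
#' tooling; a relative guard of 1e-7 absorbs floating-point ties). The
#' odds ratio is the cross-product `a*d / (b*c)`, `+Inf` when
#' `b*c == 0`.
#'
#' @param a,b Case-group counts of the two alleles.
#' @param c,d Control-group counts of the two alleles.
#' @return A list with `p_value` and `odds_ratio`.
#' @examples
#' fisher_allelic(5, 5, 5, 5)$p_value  # 1
#' @export
fisher_allelic <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("fisher_allelic: counts must be non-negative integers")
  }
  if (a + b == 0 || c + d == 0) {
    abort("fisher_allelic: both group margins must be positive")
  }
  m <- a + b
  n2 <- c + d
  K <- a + c
  x <- max(0, K - n2):min(K, m)
  pr <- dhyper(x, m, n2, K)
  p_obs <- pr[match(a, x)]
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  list(p_value = p, odds_ratio = or)
}

#' Genotype-matrix quality control
#'
#' Sequentially removes (strict thresholds, exactly as conventionally
#' printed):
#'
#' 1. individuals with genotype missing rate `>= max_missing_per_individual`
#'    (keep `< 0.1`);
#' 2. SNPs with missing rate `>= max_missing_per_snp` (keep `< 0.5`),
#'    computed on the surviving individuals;
#' 3. SNPs whose exact HWE p-value is `<= min_hwe_p` (keep `> 0.001`),
#'    computed on all genotyped surviving individuals (cases and
#'    controls combined).
#'
#' The step order is overridable; the removal ledger together with the
#' surviving matrix accounts for every input row and column.
#'
#' @param gm A [genotype_matrix()].
#' @param thresholds The `qc` element of [heat_config()].
#' @param order Character vector permuting
#'   `c("individuals", "snp_missing", "hwe")`.
#' @return A list with `matrix` (the filtered `geno_matrix`) and
#'   `removed` (tibble: `type`, `id`, `reason`, `value`, `threshold`).
#' @export
qc_genotypes <- function(gm, thresholds = heat_config()$qc,
                         order = c("individuals", "snp_missing", "hwe")) {
  stopifnot(inherits(gm, "geno_matrix"))
  stopifnot(setequal(order, c("individuals", "snp_missing", "hwe")))
  th <- thresholds
  calls <- gm$calls
  snps <- gm$snps
  removed <- tibble(type = character(), id = character(),
                    reason = character(), value = double(),
                    threshold = double())
  geno_cols <- function() setdiff(names(calls), "individual_id")

  drop_individuals <- function() {
    g <- as.matrix(calls[geno_cols()])
    rate <- rowMeans(is.na(g))
    bad <- rate >= th$max_missing_per_individual
    if (any(bad)) {
      removed <<- bind_rows(removed, tibble(
        type = "individual", id = calls$individual_id[bad],
        reason = "missing_rate", value = rate[bad],
        threshold = th$max_missing_per_individual))
      calls <<- calls[!bad, , drop = FALSE]
    }
  }
  drop_snps_missing <- function() {
    g <- as.matrix(calls[geno_cols()])
    rate <- colMeans(is.na(g))
    bad <- rate >= th$max_missing_per_snp
    if (any(bad)) {
      removed <<- bind_rows(removed, tibble(
        type = "snp", id = geno_cols()[bad], reason = "missing_rate",
        value = unname(rate[bad]), threshold = th$max_missing_per_snp))
      calls <<- calls[c("individual_id", geno_cols()[!bad])]
      snps <<- snps[snps$snp_id %in% geno_cols(), , drop = FALSE]
    }
  }
  drop_snps_hwe <- function() {
    ps <- map_dbl(geno_cols(), function(sc) {
      cnt <- genotype_counts(calls[[sc]], snps[snps$snp_id == sc, ])
      if (sum(cnt) == 0) return(NA_real_)
      hwe_exact(cnt[1], cnt[2], cnt[3])
    })
    bad <- !is.na(ps) & ps <= th$min_hwe_p
    if (any(bad)) {
      removed <<- bind_rows(removed, tibble(
        type = "snp", id = geno_cols()[bad], reason = "hwe",
        value = ps[bad], threshold = th$min_hwe_p))
      calls <<- calls[c("individual_id", geno_cols()[!bad])]
      snps <<- snps[snps$snp_id %in% geno_cols(), , drop = FALSE]
    }
  }
  for (step in order) {
    switch(step,
           individuals = drop_individuals(),
           snp_missing = drop_snps_missing(),
           hwe = drop_snps_hwe())
  }
  if (nrow(calls) == 0 || length(geno_cols()) == 0) {
    abort(paste0("qc_genotypes: empty matrix after QC (",
                 nrow(removed), " removals; inspect the ledger)"),
          ledger = removed)
  }
  hs_log("qc_genotypes: kept ", nrow(calls), " individuals x ",
         length(geno_cols()), " SNPs (", nrow(removed), " removals)")
  list(matrix = genotype_matrix(calls, snps), removed = removed)
}

# internal: genotype counts (hom a1, het, hom a2) for one SNP column
genotype_counts <- function(geno, snp_row) {
  g <- geno[!is.na(geno)]
  if (length(g) == 0 || is.na(snp_row$a1)) return(c(0L, 0L, 0L))
  a1 <- snp_row$a1
  a2 <- snp_row$a2
  hom1 <- paste0(a1, a1)
  hom2 <- paste0(a2, a2)
  het <- normalize_gt(paste0(a1, a2))
  c(sum(g == hom1), sum(g == het & a1 != a2), sum(g == hom2 & a2 != a1))
}

#' Reconstruct allele counts from a printed frequency
#'
#' Published association tables often print group allele frequencies to
#' 3-4 decimals without the underlying counts. This utility enumerates
#' even allele totals n in `[n_min, n_max]` (a group of up to k diploid
#' individuals contributes an even number of alleles) and integer
#' counts k such that `k/n` rounds (half-up, to `decimals` places) to
#' the printed value, and returns the pair with the largest valid n
#' (the least-missing-data explanation). When several (k, n) pairs
#' match, the result is flagged ambiguous and all matches are returned.
#'
#' @param freq Printed frequency in `[0, 1]`.
#' @param decimals Number of printed decimal places.
#' @param n_min,n_max Even bounds on the allele total.
#' @return A list with `k`, `n`, `ambiguous` and a `matches` tibble.
#' @examples
#' reconstruct_counts(0.3404, 4)  # k = 32, n = 94
#' @export
reconstruct_counts <- function(freq, decimals, n_min = 48, n_max = 96) {
  if (freq < 0 || freq > 1) abort("reconstruct_counts: frequency outside [0, 1]")
  if (n_min %% 2 != 0 || n_max %% 2 != 0) {
    abort("reconstruct_counts: n_min and n_max must be even")
  }
  tol <- 0.5 * 10^(-decimals) + 1e-12
  matches <- list()
  for (n in seq(n_min, n_max, by = 2)) {
    k_lo <- max(0, ceiling((freq - tol) * n))
    k_hi <- min(n, floor((freq + tol) * n))
    for (kk in seq_len(max(0, k_hi - k_lo + 1)) + k_lo - 1) {
      if (abs(kk / n - freq) <= tol) {
        matches[[length(matches) + 1]] <- tibble(k = kk, n = n)
      }
    }
  }
  if (length(matches) == 0) {
    abort(paste0("reconstruct_counts: no (k, n) with even n in [", n_min,
                 ", ", n_max, "] rounds to ", freq))
  }
  m <- bind_rows(matches) |> distinct() |> arrange(.data$n, .data$k)
  best <- m[nrow(m), ]
  list(k = best$k, n = best$n, ambiguous = nrow(m) > 1, matches = m)
}

#' Allelic case-control association across a SNP panel
#'
#' For every SNP, tallies the two declared alleles in the case and
#' control groups (two alleles per genotyped individual; missing calls
#' skipped) and applies [fisher_allelic()]. SNPs monomorphic across the
#' combined groups are skipped with a ledger entry. Results are sorted
#' by p-value.
#'
#' @param gm A (QC'd) [genotype_matrix()].
#' @param case_ids,control_ids Disjoint character vectors of individual
#'   ids (e.g. the susceptible and resistant extremes).
#' @return An object of class `heat_assoc`; see [tidy.heat_assoc()].
#' @export
run_association <- function(gm, case_ids, control_ids) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (length(intersect(case_ids, control_ids)) > 0) {
    abort("run_association: case and control groups overlap")
  }
  missing_ids <- setdiff(c(case_ids, control_ids), gm$calls$individual_id)
  if (length(missing_ids) > 0) {
    abort(paste0("run_association: unknown individual id(s): ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  cases <- gm$calls[gm$calls$individual_id %in% case_ids, , drop = FALSE]
  controls <- gm$calls[gm$calls$individual_id %in% control_ids, , drop = FALSE]
  allele_count <- function(geno, allele) {
    g <- geno[!is.na(geno)]
    sum(substr(g, 1, 1) == allele) + sum(substr(g, 2, 2) == allele)
  }
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(gm$snps))) {
    s <- gm$snps[i, ]
    if (is.na(s$a1)) {
      skipped[[length(skipped) + 1]] <-
        tibble(snp_id = s$snp_id, reason = "all_missing")
      next
    }
    a <- allele_count(cases[[s$snp_id]], s$a1)
    b <- allele_count(cases[[s$snp_id]], s$a2)
    c_ <- allele_count(controls[[s$snp_id]], s$a1)
    d <- allele_count(controls[[s$snp_id]], s$a2)
    if (s$a1 == s$a2 || a + c_ == 0 || b + d == 0) {
      skipped[[length(skipped) + 1]] <-
        tibble(snp_id = s$snp_id, reason = "monomorphic")
      next
    }
    if (a + b == 0 || c_ + d == 0) {
      skipped[[length(skipped) + 1]] <-
        tibble(snp_id = s$snp_id, reason = "empty_group")
      next
    }
    ft <- fisher_allelic(a, b, c_, d)
    rows[[length(rows) + 1]] <- tibble(
      snp_id = s$snp_id, allele = s$a1,
      freq_case = a / (a + b), freq_control = c_ / (c_ + d),
      n_case = a + b, n_control = c_ + d,
      a = a, b = b, c = c_, d = d,
      odds_ratio = ft$odds_ratio, p_value = ft$p_value
    )
  }
  results <- if (length(rows) > 0) {
    arrange(bind_rows(rows), .data$p_value)
  } else {
    tibble(snp_id = character(), allele = character(),
           freq_case = double(), freq_control = double(),
           n_case = integer(), n_control = integer(),
           a = integer(), b = integer(), c = integer(), d = integer(),
           odds_ratio = double(), p_value = double())
  }
  hs_log("run_association: ", nrow(results), " SNPs tested, ",
         length(skipped), " skipped")
  structure(
    list(results = results,
         skipped = if (length(skipped) > 0) bind_rows(skipped) else
           tibble(snp_id = character(), reason = character()),
         n_case = length(case_ids), n_control = length(control_ids)),
    class = "heat_assoc"
  )
}

#' @export
print.heat_assoc <- function(x, ...) {
  cat("<heat_assoc> ", nrow(x$results), " SNPs tested (",
      x$n_case, " cases / ", x$n_control, " controls), ",
      nrow(x$skipped), " skipped\n", sep = "")
  print(head(x$results, 10))
  invisible(x)
}

#' Tidy an association result
#'
#' @param x A `heat_assoc` object.
#' @param ... Unused.
#' @return The per-SNP results tibble, sorted by p-value, with columns
#'   `snp_id`, tested `allele`, case/control frequencies and counts,
#'   `odds_ratio` and two-sided Fisher `p_value`.
#' @export
tidy.heat_assoc <- function(x, ...) x$results

#' One-row summary of an association result
#'
#' @param x A `heat_assoc` object.
#' @param ... Unused.
#' @return A tibble with the number of SNPs tested and skipped, group
#'   sizes, the smallest p-value and its SNP, and the count of SNPs
#'   with p < 0.05.
#' @export
glance.heat_assoc <- function(x, ...) {
  tibble(
    n_tested = nrow(x$results),
    n_skipped = nrow(x$skipped),
    n_case = x$n_case,
    n_control = x$n_control,
    min_p = if (nrow(x$results) > 0) min(x$results$p_value) else NA_real_,
    top_snp = if (nrow(x$results) > 0) x$results$snp_id[1] else NA_character_,
    n_p_lt_05 = sum(x$results$p_value < 0.05)
  )
}

#' Association p-value plot
#'
#' -log10 p per SNP, with a reference line at p = 0.05.
#'
#' @param object A `heat_assoc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heat_assoc <- function(object, ...) {
  df <- mutate(object$results, rank = row_number())
  ggplot(df, aes(x = stats::reorder(.data$snp_id, .data$rank),
                 y = -log10(.data$p_value))) +
    geom_point(colour = "firebrick") +
    geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    labs(x = NULL, y = expression(-log[10](italic(p))),
         title = "Allelic case-control association") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1, size = 7))
}
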