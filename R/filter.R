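# Post-call quality filters. A consensus caller emits one row per variant
# site per population pool; these rules discard unreliable calls before
# cross-population classification.

#' Apply per-call quality rules
#'
#' A call is kept iff all of the following hold:
#'
#' * (a) genotype score >= `min_genotype_score`;
#' * (b) `depth_low` < sequencing depth < `depth_high` (both bounds
#'   rejecting, i.e. depth 10 is rejected and depth 11 kept at the
#'   defaults);
#' * (c) for heterozygous calls, the minor genotype allele has read depth
#'   >= `min_minor_depth` and depth-based minor allele frequency
#'   (minor depth / total allele depth at the site) >= `min_maf`.
#'
#' Rules are evaluated in the fixed order (a), (b), (c: minor depth,
#' then MAF); the ledger records the first failing rule per rejected
#' call, though the kept set itself is order-independent.
#'
#' @param calls Variant-call tibble (see [read_variant_calls()]).
#' @param thresholds The `quality` element of [heat_config()].
#' @return A list with elements `kept` (tibble of surviving calls) and
#'   `rejected` (ledger tibble: `snp_id`, `rule`, `observed`,
#'   `threshold`).
#' @export
filter_quality <- function(calls, thresholds = heat_config()$quality) {
  calls <- validate_variant_calls(calls, source = "filter_quality input")
  th <- thresholds
  if (nrow(calls) == 0) {
    return(list(kept = calls, rejected = empty_ledger()))
  }
  al <- gt_alleles(calls$genotype)
  het <- al[, 1] != al[, 2]
  ad <- as.matrix(calls[paste0("depth_", DNA_BASES)])
  d1 <- ad[cbind(seq_len(nrow(calls)), match(al[, 1], DNA_BASES))]
  d2 <- ad[cbind(seq_len(nrow(calls)), match(al[, 2], DNA_BASES))]
  if (any(het & (is.na(d1) | is.na(d2)))) {
    bad <- which(het & (is.na(d1) | is.na(d2)))[1]
    abort(paste0("heterozygous call with genotype allele absent from ",
                 "allele depths at ", snp_id(calls$unigene_id[bad],
                                             calls$pos[bad])))
  }
  minor <- pmin(d1, d2)
  total_ad <- rowSums(ad)
  maf <- ifelse(total_ad > 0, minor / total_ad, 0)

  fail_a <- calls$score < th$min_genotype_score
  fail_b <- calls$depth <= th$depth_low | calls$depth >= th$depth_high
  fail_c_minor <- het & minor < th$min_minor_depth
  fail_c_maf <- het & maf < th$min_maf

  rule <- rep(NA_character_, nrow(calls))
  observed <- rep(NA_real_, nrow(calls))
  threshold <- rep(NA_real_, nrow(calls))
  take <- function(cond, label, obs, thr) {
    sel <- cond & is.na(rule)
    rule[sel] <<- label
    observed[sel] <<- obs[sel]
    threshold[sel] <<- thr
  }
  take(fail_a, "genotype_score", calls$score, th$min_genotype_score)
  take(fail_b, "depth", as.numeric(calls$depth), th$depth_low)
  take(fail_c_minor, "minor_depth", as.numeric(minor), th$min_minor_depth)
  take(fail_c_maf, "maf", maf, th$min_maf)

  rejected_idx <- !is.na(rule)
  ledger <- tibble(
    snp_id = snp_id(calls$unigene_id[rejected_idx], calls$pos[rejected_idx]),
    rule = rule[rejected_idx],
    observed = observed[rejected_idx],
    threshold = threshold[rejected_idx]
  )
  hs_log("filter_quality: kept ", sum(!rejected_idx), "/", nrow(calls))
  list(kept = calls[!rejected_idx, , drop = FALSE], rejected = ledger)
}

# internal
empty_ledger <- function() {
  tibble(snp_id = character(), rule = character(),
         observed = double(), threshold = double())
}

#' Apply the SNP-density rule
#'
#' A call is rejected iff more than `density_max_snps` calls (itself
#' included) fall within the closed window of `density_window_bp` bp
#' centred on it (`[pos - w/2, pos + w/2]`, `w/2 = 25` bp at the
#' default) on the same unigene. The rule is applied in a single pass on
#' its input set: removals do not trigger re-counting, because a removal
#' cascade is not part of the rule.
#'
#' @param calls Variant-call tibble, usually the `kept` set of
#'   [filter_quality()].
#' @param thresholds The `quality` element of [heat_config()].
#' @return A list with `kept` and `rejected` tibbles as in
#'   [filter_quality()].
#' @export
filter_density <- function(calls, thresholds = heat_config()$quality) {
  th <- thresholds
  if (nrow(calls) == 0) {
    return(list(kept = calls, rejected = empty_ledger()))
  }
  hw <- floor(th$density_window_bp / 2)
  counts <- integer(nrow(calls))
  for (ug in unique(calls$unigene_id)) {
    idx <- which(calls$unigene_id == ug)
    p <- calls$pos[idx]
    o <- order(p)
    ps <- p[o]
    # windowed neighbour count via binary search on the sorted positions
    n_in <- findInterval(ps + hw, ps) - findInterval(ps - hw - 1L, ps)
    counts[idx[o]] <- n_in
  }
  rejected_idx <- counts > th$density_max_snps
  ledger <- tibble(
    snp_id = snp_id(calls$unigene_id[rejected_idx], calls$pos[rejected_idx]),
    rule = "density",
    observed = as.numeric(counts[rejected_idx]),
    threshold = as.numeric(th$density_max_snps)
  )
  hs_log("filter_density: kept ", sum(!rejected_idx), "/", nrow(calls))
  list(kept = calls[!rejected_idx, , drop = FALSE], rejected = ledger)
}

#' Run the full post-call filter chain
#'
#' [filter_quality()] followed by [filter_density()] (density counted on
#' the post-quality SNP set), with a combined rejection ledger.
#'
#' @inheritParams filter_quality
#' @return A list with `kept` and `rejected`.
#' @export
filter_variants <- function(calls, thresholds = heat_config()$quality) {
  q <- filter_quality(calls, thresholds)
  d <- filter_density(q$kept, thresholds)
  list(kept = d$kept, rejected = bind_rows(q$rejected, d$rejected))
}
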