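# Allelic imbalance between the pooled populations: pooled allele
# frequencies are estimated from per-site read depths, and the ratio of
# the focal allele's frequency between the northern and southern pools is
# thresholded (inclusive >= 5 or <= 0.2) to flag imbalanced SNPs.

#' Pooled allele frequency from read depths
#'
#' The frequency of a focal allele in a sequencing pool, estimated as
#' its read depth over the total allele depth at the site.
#'
#' @param allele_depths Named numeric vector of per-base read counts,
#'   e.g. `c(A = 0, C = 12, G = 0, T = 18)`.
#' @param focal Focal allele (single base). A base absent from the
#'   vector counts as depth 0.
#' @return Frequency in `[0, 1]`.
#' @examples
#' pooled_allele_freq(c(T = 18, C = 12), "C")  # 0.4
#' @export
pooled_allele_freq <- function(allele_depths, focal) {
  total <- sum(allele_depths)
  if (total <= 0) abort("pooled_allele_freq: zero total allele depth")
  fd <- allele_depths[focal]
  fd <- if (is.na(fd)) 0 else unname(fd)
  fd / total
}

#' Allelic imbalance score
#'
#' The ratio of the focal allele's pooled frequency between the northern
#' and southern populations, `f_north / f_south`. A frequency that is
#' zero only in the south gives `+Inf` (maximally imbalanced); both
#' frequencies zero is undefined and an error.
#'
#' @param f_north,f_south Pooled frequencies in `[0, 1]`.
#' @return Numeric score (possibly `Inf`). Vectorized.
#' @examples
#' imbalance_score(0.5, 0.1)  # 5
#' @export
imbalance_score <- function(f_north, f_south) {
  if (any(f_north < 0 | f_north > 1 | f_south < 0 | f_south > 1)) {
    abort("imbalance_score: frequencies must lie in [0, 1]")
  }
  if (any(f_north == 0 & f_south == 0)) {
    abort("imbalance_score: both frequencies zero; score undefined")
  }
  ifelse(f_south == 0, Inf, f_north / f_south)
}

#' Flag imbalanced scores
#'
#' Inclusive thresholds: a score `>= high` or `<= low` is imbalanced
#' (defaults 5 and 0.2, which are reciprocal, making the flag invariant
#' to which allele of a biallelic site is taken as focal).
#'
#' @param score Numeric vector of imbalance scores.
#' @param thresholds The `imbalance` element of [heat_config()].
#' @return Logical vector.
#' @export
is_imbalanced <- function(score, thresholds = heat_config()$imbalance) {
  score >= thresholds$high | score <= thresholds$low
}

#' Score allelic imbalance for classified SNPs
#'
#' Joins per-pool read depths onto the classified site list, estimates
#' the focal (non-reference) allele's pooled frequency in each
#' population and computes the north/south imbalance score. By default
#' only SNPs of the shared categories are evaluated (the categories for
#' which both pools segregate and a frequency ratio is informative);
#' `restrict_to_shared = FALSE` scores every site that has positive
#' allele depth in both pools.
#'
#' Sites whose total allele depth in either pool is below `min_depth`
#' (default: the quality filter's `depth_low`) are dropped to avoid
#' ratio noise; dropped sites are reported in the `skipped` attribute.
#'
#' @param classified Output of [classify_snps()].
#' @param north_calls,south_calls The filtered call tibbles the
#'   classification was built from (for allele depths).
#' @param thresholds The `imbalance` element of [heat_config()].
#' @param min_depth Minimum per-pool total allele depth.
#' @return A tibble: `snp_id`, `category`, `focal`, `f_north`,
#'   `f_south`, `score`, `imbalanced`.
#' @export
score_imbalance <- function(classified, north_calls, south_calls,
                            thresholds = heat_config()$imbalance,
                            min_depth = heat_config()$quality$depth_low) {
  restrict <- isTRUE(thresholds$restrict_to_shared)
  sites <- filter(classified, !is.na(.data$category))
  if (restrict) {
    sites <- filter(sites, grepl("^shared", .data$category))
  }
  depth_cols <- paste0("depth_", DNA_BASES)
  grab <- function(calls, side) {
    sel <- calls[c("unigene_id", "pos", depth_cols)]
    names(sel)[3:6] <- paste0(side, "_", DNA_BASES)
    sel
  }
  x <- sites |>
    left_join(grab(north_calls, "n"), by = c("unigene_id", "pos")) |>
    left_join(grab(south_calls, "s"), by = c("unigene_id", "pos"))
  # focal allele: alphabetically first non-reference allele observed at
  # the site (for biallelic sites, the unique alternative allele)
  focal <- map_chr(seq_len(nrow(x)), function(i) {
    al <- setdiff(sort(unique(c(gt_alleles(x$north_gt[i]),
                                gt_alleles(x$south_gt[i])))), x$ref[i])
    if (length(al) == 0) NA_character_ else al[1]
  })
  nmat <- as.matrix(x[paste0("n_", DNA_BASES)])
  smat <- as.matrix(x[paste0("s_", DNA_BASES)])
  nmat[is.na(nmat)] <- 0
  smat[is.na(smat)] <- 0
  n_tot <- rowSums(nmat)
  s_tot <- rowSums(smat)
  fi <- match(focal, DNA_BASES)
  ok <- !is.na(fi) & n_tot >= min_depth & s_tot >= min_depth
  f_n <- ifelse(ok, nmat[cbind(seq_len(nrow(x)), fi)] / n_tot, NA_real_)
  f_s <- ifelse(ok, smat[cbind(seq_len(nrow(x)), fi)] / s_tot, NA_real_)
  defined <- ok & !(f_n == 0 & f_s == 0)
  score <- rep(NA_real_, nrow(x))
  score[defined] <- ifelse(f_s[defined] == 0, Inf,
                           f_n[defined] / f_s[defined])
  out <- tibble(
    snp_id = x$snp_id,
    category = x$category,
    focal = focal,
    f_north = f_n,
    f_south = f_s,
    score = score,
    imbalanced = ifelse(is.na(score), NA, is_imbalanced(score, thresholds))
  )
  skipped <- out$snp_id[is.na(out$score)]
  out <- filter(out, !is.na(.data$score))
  attr(out, "skipped") <- skipped
  hs_log("score_imbalance: ", nrow(out), " SNPs scored, ",
         sum(out$imbalanced), " imbalanced, ", length(skipped), " skipped")
  out
}
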