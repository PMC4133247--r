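# Cross-population SNP classification. Each site called in at least one
# population pool is compared against the unigene reference base and the
# other pool's genotype, and assigned one of the categories used for
# diverged-subspecies pooled sequencing:
#   inter_subspecific  both pools homozygous for different non-reference
#                      alleles
#   shared_same_het    both pools heterozygous with the same allele pair
#   shared_diff_het    both pools heterozygous with different allele pairs
#   north_specific     only the northern pool segregates / differs
#   south_specific     only the southern pool segregates / differs
# Both shared_* categories aggregate to "shared" in four-way reporting.

SNP_CATEGORIES <- c("inter_subspecific", "shared_same_het", "shared_diff_het",
                    "north_specific", "south_specific")

IUPAC_MAP <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' IUPAC ambiguity code for a diploid genotype
#'
#' Homozygotes map to the base itself; heterozygotes to the standard
#' ambiguity code (M = A/C, R = A/G, W = A/T, S = C/G, Y = C/T,
#' K = G/T). [iupac_decode()] is the inverse.
#'
#' @param genotype Character vector of two-letter genotype strings (or a
#'   length-2 vector of bases for a single genotype).
#' @return Character vector of single-character codes.
#' @examples
#' iupac_code("TG")      # "K"
#' iupac_code(c("A","C")) # "M"
#' @export
iupac_code <- function(genotype) {
  if (length(genotype) == 2 && all(nchar(genotype) == 1)) {
    genotype <- paste0(genotype[1], genotype[2])
  }
  gt <- normalize_gt(genotype)
  al <- gt_alleles(gt)
  if (any(!(al %in% DNA_BASES) & !is.na(al))) {
    abort("iupac_code: genotype contains a non-ACGT base")
  }
  out <- ifelse(al[, 1] == al[, 2], al[, 1], unname(IUPAC_MAP[gt]))
  out
}

#' Decode an IUPAC code to its allele pair
#'
#' @param code Character vector of single IUPAC characters (plain bases
#'   or two-base ambiguity codes).
#' @return For a single code, a character vector of the two alleles; for
#'   several, a list of such vectors.
#' @examples
#' iupac_decode("M")  # c("A","C")
#' @export
iupac_decode <- function(code) {
  dec <- function(cc) {
    if (cc %in% DNA_BASES) return(c(cc, cc))
    hit <- names(IUPAC_MAP)[IUPAC_MAP == cc]
    if (length(hit) == 0) abort(paste0("iupac_decode: unknown code '", cc, "'"))
    c(substr(hit, 1, 1), substr(hit, 2, 2))
  }
  if (length(code) == 1) dec(code) else purrr::map(code, dec)
}

# internal vectorized classification core; ngt/sgt must be normalized
# two-letter strings with absence already resolved (no NAs).
classify_core <- function(ref, ngt, sgt) {
  nal <- gt_alleles(ngt)
  sal <- gt_alleles(sgt)
  n_het <- nal[, 1] != nal[, 2]
  s_het <- sal[, 1] != sal[, 2]
  n_hom_ref <- !n_het & nal[, 1] == ref
  s_hom_ref <- !s_het & sal[, 1] == ref

  category <- rep(NA_character_, length(ref))
  note <- rep(NA_character_, length(ref))

  bh <- !n_het & !s_het
  category[bh & n_hom_ref & !s_hom_ref] <- "south_specific"
  category[bh & !n_hom_ref & s_hom_ref] <- "north_specific"
  inter <- bh & !n_hom_ref & !s_hom_ref & nal[, 1] != sal[, 1]
  category[inter] <- "inter_subspecific"
  mono <- bh & !n_hom_ref & !s_hom_ref & nal[, 1] == sal[, 1]
  note[mono] <- "monomorphic_nonref"
  note[bh & n_hom_ref & s_hom_ref] <- "reference"

  bht <- n_het & s_het
  category[bht & ngt == sgt] <- "shared_same_het"
  category[bht & ngt != sgt] <- "shared_diff_het"

  nh_sh <- n_het & !s_het
  category[nh_sh] <- "north_specific"
  note[nh_sh & !s_hom_ref] <- "het_vs_hom_nonref"
  sh_nh <- !n_het & s_het
  category[sh_nh] <- "south_specific"
  note[sh_nh & !n_hom_ref] <- "het_vs_hom_nonref"

  tibble(category = category, note = note)
}

#' Classify one site across the two population pools
#'
#' @param ref Reference base at the site.
#' @param north,south Pool genotypes as two-letter strings, or `NA` when
#'   the pool made no call at the site. At least one pool must have a
#'   call. By default an absent call is interpreted as
#'   homozygous-reference (a consensus caller only reports sites that
#'   differ from the reference); with `absent_as_ref = FALSE` such sites
#'   are skipped (category `NA`, note `"absent_pool"`).
#' @param absent_as_ref Treat a missing pool call as hom-reference.
#' @return A list with elements `category` (one of
#'   `r paste(SNP_CATEGORIES, collapse = ", ")`, or `NA` when the site is
#'   no between-pool SNP) and `note` (sub-flag for combinations outside
#'   the four-way scheme, e.g. `"het_vs_hom_nonref"`,
#'   `"monomorphic_nonref"`).
#' @examples
#' classify_site("A", "GG", "AA")$category  # north_specific
#' classify_site("A", "GG", "TT")$category  # inter_subspecific
#' @export
classify_site <- function(ref, north = NA, south = NA, absent_as_ref = TRUE) {
  if (!ref %in% DNA_BASES) abort("classify_site: non-ACGT reference base")
  if (is.na(north) && is.na(south)) {
    abort("classify_site: both pools absent at the site")
  }
  if (!absent_as_ref && (is.na(north) || is.na(south))) {
    return(list(category = NA_character_, note = "absent_pool"))
  }
  ngt <- if (is.na(north)) paste0(ref, ref) else normalize_gt(north)
  sgt <- if (is.na(south)) paste0(ref, ref) else normalize_gt(south)
  for (g in c(ngt, sgt)) {
    if (!all(gt_alleles(g) %in% DNA_BASES)) {
      abort("classify_site: genotype contains a non-ACGT base")
    }
  }
  res <- classify_core(ref, ngt, sgt)
  list(category = res$category, note = res$note)
}

#' Classify all sites from two filtered call lists
#'
#' Joins the two pools' calls by (unigene, position), resolves absent
#' pools, and classifies every site. Sites where the two pools disagree
#' on the reference allele are an error.
#'
#' @param north_calls,south_calls Filtered variant-call tibbles.
#' @param absent_as_ref See [classify_site()].
#' @return A tibble with one row per site: `unigene_id`, `pos`, `snp_id`,
#'   `ref`, `north_gt`, `south_gt`, their IUPAC codes, `category`,
#'   `note`. Per-category counts are attached as attribute `"counts"`
#'   and reported via [category_counts()].
#' @export
classify_snps <- function(north_calls, south_calls, absent_as_ref = TRUE) {
  pick <- function(calls, side) {
    out <- if (nrow(calls) == 0) {
      tibble(unigene_id = character(), pos = integer(),
             ref = character(), gt = character())
    } else {
      tibble(unigene_id = calls$unigene_id, pos = calls$pos,
             ref = calls$ref, gt = normalize_gt(calls$genotype))
    }
    setNames(out, c("unigene_id", "pos", paste0("ref_", side),
                    paste0(side, "_gt")))
  }
  joined <- full_join(pick(north_calls, "north"), pick(south_calls, "south"),
                      by = c("unigene_id", "pos"))
  if (nrow(joined) == 0) {
    out <- tibble(unigene_id = character(), pos = integer(),
                  snp_id = character(), ref = character(),
                  north_gt = character(), south_gt = character(),
                  north_iupac = character(), south_iupac = character(),
                  category = character(), note = character())
    attr(out, "counts") <- setNames(integer(length(SNP_CATEGORIES)),
                                    SNP_CATEGORIES)
    return(out)
  }
  conflict <- !is.na(joined$ref_north) & !is.na(joined$ref_south) &
    joined$ref_north != joined$ref_south
  if (any(conflict)) {
    i <- which(conflict)[1]
    abort(paste0("conflicting reference allele at ",
                 snp_id(joined$unigene_id[i], joined$pos[i]), ": north '",
                 joined$ref_north[i], "' vs south '", joined$ref_south[i], "'"))
  }
  ref <- coalesce(joined$ref_north, joined$ref_south)
  north_gt <- joined$north_gt
  south_gt <- joined$south_gt
  if (absent_as_ref) {
    hom_ref <- paste0(ref, ref)
    north_gt <- coalesce(north_gt, hom_ref)
    south_gt <- coalesce(south_gt, hom_ref)
    res <- classify_core(ref, north_gt, south_gt)
  } else {
    res <- tibble(category = NA_character_, note = "absent_pool",
                  .rows = nrow(joined))
    both <- !is.na(north_gt) & !is.na(south_gt)
    if (any(both)) {
      res[both, ] <- classify_core(ref[both], north_gt[both], south_gt[both])
    }
  }
  out <- tibble(
    unigene_id = joined$unigene_id,
    pos = joined$pos,
    snp_id = snp_id(joined$unigene_id, joined$pos),
    ref = ref,
    north_gt = north_gt,
    south_gt = south_gt,
    north_iupac = iupac_code(north_gt),
    south_iupac = iupac_code(south_gt),
    category = res$category,
    note = res$note
  ) |> arrange(.data$unigene_id, .data$pos)
  counts <- table(factor(out$category, levels = SNP_CATEGORIES))
  attr(out, "counts") <- setNames(as.integer(counts), SNP_CATEGORIES)
  hs_log("classify_snps: ", sum(!is.na(out$category)), " classified sites (",
         paste(names(counts), as.integer(counts), sep = "=", collapse = ", "),
         ")")
  out
}

#' Per-category SNP counts
#'
#' @param classified Output of [classify_snps()].
#' @param four_way Aggregate the two shared heterozygosity types into a
#'   single `shared` class (the four-way reporting convention).
#' @return A tibble with `category` and `n`.
#' @export
category_counts <- function(classified, four_way = FALSE) {
  counts <- attr(classified, "counts")
  if (is.null(counts)) {
    counts <- table(factor(classified$category, levels = SNP_CATEGORIES))
    counts <- setNames(as.integer(counts), SNP_CATEGORIES)
  }
  out <- tibble(category = names(counts), n = as.integer(counts))
  if (four_way) {
    out <- out |>
      mutate(category = ifelse(grepl("^shared", .data$category),
                               "shared", .data$category)) |>
      group_by(.data$category) |>
      summarise(n = sum(.data$n), .groups = "drop")
  }
  out
}

#' Bar chart of SNP category counts
#'
#' @param classified Output of [classify_snps()].
#' @return A ggplot object.
#' @export
plot_snp_categories <- function(classified) {
  category_counts(classified) |>
    ggplot(aes(x = .data$category, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "SNPs", title = "Cross-population SNP categories") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}
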