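# Candidate-gene selection: unigenes annotated to the protein families
# known to matter for thermal tolerance (heat shock proteins, antioxidant
# enzymes, the ubiquitin-proteasome system) plus unigenes carrying
# allelically imbalanced SNPs; their SNPs are then screened for
# high-resolution-melting (HRM) assay feasibility.

#' Default annotation keyword groups
#'
#' Substring/regex patterns (matched case-insensitively against the
#' free-text annotation) for the three protein families used to nominate
#' heat-tolerance candidate genes: heat shock proteins, antioxidant
#' activity (superoxide dismutase, peroxidase, thioredoxin, the
#' glutathione redox system) and the ubiquitin-proteasome system.
#'
#' @return A named list of character vectors of patterns.
#' @export
hrm_keywords <- function() {
  list(
    hsp = c("heat shock protein", "\\bhsp[0-9]"),
    antioxidant = c("superoxide dismutase", "peroxidase", "thioredoxin",
                    "glutathione"),
    ubiquitin_proteasome = c("ubiquitin", "proteasome")
  )
}

#' Select candidate genes by annotation keywords and imbalance flags
#'
#' A unigene is selected when its annotation matches any keyword pattern
#' (source `"annotation"`, labelled with the first matching keyword
#' group in list order) or when it carries an allelically imbalanced SNP
#' (source `"imbalance"`); genes qualifying both ways get source
#' `"both"`. Selection is monotone in the keyword list: adding patterns
#' can only add genes.
#'
#' @param annotation Tibble with `unigene_id` and `description`.
#' @param imbalanced_snps Optional tibble with a `snp_id` column (e.g.
#'   the imbalanced rows of [score_imbalance()] output); unigene ids are
#'   derived from the SNP ids.
#' @param keywords Named list of pattern vectors; see [hrm_keywords()].
#'   Must be non-empty.
#' @return A tibble: `unigene_id`, `source`
#'   (`annotation`/`imbalance`/`both`), `keyword_group` (`none` for
#'   imbalance-only genes).
#' @export
select_candidate_genes <- function(annotation, imbalanced_snps = NULL,
                                   keywords = hrm_keywords()) {
  if (length(keywords) == 0 || all(lengths(keywords) == 0)) {
    abort("select_candidate_genes: empty keyword config")
  }
  stopifnot(all(c("unigene_id", "description") %in% names(annotation)))
  group <- rep(NA_character_, nrow(annotation))
  for (g in names(keywords)) {
    pat <- paste(keywords[[g]], collapse = "|")
    if (nzchar(pat)) {
      hit <- grepl(pat, annotation$description, ignore.case = TRUE)
      group[is.na(group) & hit] <- g
    }
  }
  by_annot <- tibble(unigene_id = annotation$unigene_id,
                     keyword_group = group) |>
    filter(!is.na(.data$keyword_group)) |>
    distinct(.data$unigene_id, .keep_all = TRUE)
  by_imb <- tibble(unigene_id = character())
  if (!is.null(imbalanced_snps) && nrow(imbalanced_snps) > 0) {
    by_imb <- tibble(unigene_id = unique(snp_unigene(imbalanced_snps$snp_id)))
  }
  out <- full_join(mutate(by_annot, annot = TRUE),
                   mutate(by_imb, imb = TRUE), by = "unigene_id") |>
    mutate(
      source = case_when(
        !is.na(.data$annot) & !is.na(.data$imb) ~ "both",
        !is.na(.data$annot) ~ "annotation",
        TRUE ~ "imbalance"
      ),
      keyword_group = coalesce(.data$keyword_group, "none")
    ) |>
    select("unigene_id", "source", "keyword_group") |>
    arrange(.data$unigene_id)
  hs_log("select_candidate_genes: ", nrow(out), " candidate unigenes")
  out
}

#' HRM-assay feasibility of a single SNP
#'
#' High-resolution melting genotypes a SNP by the melting-curve shape of
#' a small amplicon; the assay fails when (checked in this fixed order):
#'
#' 1. `fail_flanking_snp` -- another SNP lies within the closed window
#'    `[pos - flank_bp, pos + flank_bp]` on the same unigene (its
#'    melting signal would confound the target's);
#' 2. `fail_at_gc_transversion` -- the allele pair is A/T or G/C, whose
#'    amplicon melting temperatures are indistinguishable;
#' 3. `fail_no_amplicon_window` -- no window with length in
#'    `[amplicon_min, amplicon_max]` containing the SNP fits within the
#'    unigene.
#'
#' A SNP failing several rules reports the first.
#'
#' @param pos 1-based SNP position on the unigene.
#' @param alleles The SNP's two alleles (two-letter string or length-2
#'   vector).
#' @param snp_positions Positions of all SNPs on the same unigene
#'   (the focal SNP itself may be included or not).
#' @param unigene_length Length of the unigene in bp.
#' @param thresholds The `hrm` element of [heat_config()].
#' @return One of `"pass"`, `"fail_flanking_snp"`,
#'   `"fail_at_gc_transversion"`, `"fail_no_amplicon_window"`.
#' @export
hrm_feasibility <- function(pos, alleles, snp_positions, unigene_length,
                            thresholds = heat_config()$hrm) {
  th <- thresholds
  if (length(alleles) == 1) alleles <- gt_alleles(normalize_gt(alleles))[1, ]
  others <- snp_positions[snp_positions != pos]
  if (any(abs(others - pos) <= th$flank_bp)) {
    return("fail_flanking_snp")
  }
  pair <- paste(sort(alleles), collapse = "")
  if (pair %in% c("AT", "CG")) {
    return("fail_at_gc_transversion")
  }
  # an amplicon window of some feasible length L must contain pos and fit
  # in [1, unigene_length]; equivalent to: for some L in range, a start
  # s with max(1, pos - L + 1) <= s <= min(pos, unigene_length - L + 1)
  feasible <- FALSE
  for (L in th$amplicon_min:th$amplicon_max) {
    lo <- max(1L, pos - L + 1L)
    hi <- min(pos, unigene_length - L + 1L)
    if (lo <= hi) { feasible <- TRUE; break }
  }
  if (!feasible) return("fail_no_amplicon_window")
  "pass"
}

#' Screen classified SNPs for HRM feasibility
#'
#' Applies [hrm_feasibility()] to every SNP of the given unigenes, using
#' the full per-unigene SNP list for the flanking rule. The allele pair
#' tested is the union of non-identical alleles across the two pool
#' genotypes (for biallelic sites, reference + alternative).
#'
#' @param classified Output of [classify_snps()] (rows with `NA`
#'   category are ignored).
#' @param reference Reference tibble (for unigene lengths), or a named
#'   numeric vector of lengths.
#' @param thresholds The `hrm` element of [heat_config()].
#' @return `classified` rows with an added `hrm_status` column.
#' @export
screen_hrm <- function(classified, reference,
                       thresholds = heat_config()$hrm) {
  if (is.data.frame(reference)) {
    lens <- setNames(reference$length %||% nchar(reference$sequence),
                     reference$unigene_id)
  } else {
    lens <- reference
  }
  snps <- filter(classified, !is.na(.data$category))
  if (nrow(snps) == 0) return(mutate(snps, hrm_status = character(0)))
  missing_len <- setdiff(unique(snps$unigene_id), names(lens))
  if (length(missing_len) > 0) {
    abort(paste0("screen_hrm: no reference length for unigene(s): ",
                 paste(head(missing_len, 5), collapse = ", ")))
  }
  snps |>
    group_by(.data$unigene_id) |>
    mutate(hrm_status = {
      all_pos <- .data$pos
      ngt <- .data$north_gt
      sgt <- .data$south_gt
      rf <- .data$ref
      len <- lens[[.data$unigene_id[1]]]
      map_chr(seq_along(all_pos), function(i) {
        # the assayed pair: alleles observed in the pool genotypes,
        # falling back on the reference base for monomorphic-vs-ref sites
        al <- sort(unique(c(gt_alleles(ngt[i]), gt_alleles(sgt[i]))))
        if (length(al) < 2) al <- sort(unique(c(al, rf[i])))
        al <- if (length(al) >= 2) al[1:2] else c(al, al)
        hrm_feasibility(all_pos[i], al, all_pos, len, thresholds)
      })
    }) |>
    ungroup()
}
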