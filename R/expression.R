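# Expression statistics: RPKM, two-library differential-expression
# calling with FDR + fold-change rules, hypergeometric enrichment, and
# the qPCR delta-delta-CT / allele-specific efficiency-normalization
# arithmetic.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = reads * 1e9 / (gene_length_bp * total_mapped_reads)`.
#'
#' @param reads Mapped reads for the gene (vectorized).
#' @param gene_length_bp Gene length in bp (> 0).
#' @param total_mapped_reads Library total (> 0).
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(reads, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp <= 0)) abort("rpkm: gene length must be positive")
  if (any(total_mapped_reads <= 0)) abort("rpkm: library total must be positive")
  if (any(reads < 0)) abort("rpkm: negative read count")
  reads * 1e9 / (gene_length_bp * total_mapped_reads)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at
#' 1); a thin validated wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("bh_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' Per gene, a two-sided Fisher exact test on the 2x2 table of (gene
#' reads, remaining library reads) across the two libraries, followed by
#' BH adjustment across genes. A gene is differentially expressed iff
#' its adjusted p-value is below `fdr` **and** the RPKM fold change is at
#' least `min_fold` in either direction (a zero-RPKM denominator gives
#' an infinite fold, which passes; 0 vs 0 gives no fold and never
#' passes). The per-gene test statistic is pluggable via `test_fun` so
#' an alternative two-library count test can be substituted.
#'
#' @param counts Tibble with `gene_id`, `length_bp`, `reads_1`,
#'   `reads_2`.
#' @param total_1,total_2 Library totals (default: column sums).
#' @param fdr Adjusted-p threshold (strict `<`).
#' @param min_fold Minimum RPKM fold change (either direction).
#' @param test_fun Function `(a, b, c, d) -> p-value` for the per-gene
#'   2x2 count table; defaults to the two-sided Fisher exact test.
#' @return An object of class `deg_result`; `tidy()` gives the per-gene
#'   table with `rpkm_1`, `rpkm_2`, `fold_change` (library 2 over
#'   library 1), `p_value`, `p_adjusted`, `deg`.
#' @export
deg_call <- function(counts, total_1 = sum(counts$reads_1),
                     total_2 = sum(counts$reads_2),
                     fdr = heat_config()$deg$fdr,
                     min_fold = heat_config()$deg$min_fold,
                     test_fun = NULL) {
  stopifnot(all(c("gene_id", "length_bp", "reads_1", "reads_2") %in%
                  names(counts)))
  if (total_1 <= 0 || total_2 <= 0) abort("deg_call: library totals must be positive")
  if (any(counts$reads_1 > total_1) || any(counts$reads_2 > total_2)) {
    abort("deg_call: gene reads exceed library total")
  }
  if (is.null(test_fun)) {
    test_fun <- function(a, b, c, d) fisher_allelic(a, b, c, d)$p_value
  }
  r1 <- rpkm(counts$reads_1, counts$length_bp, total_1)
  r2 <- rpkm(counts$reads_2, counts$length_bp, total_2)
  fold <- r2 / r1                      # Inf when r1 == 0, NaN when both 0
  p <- map_dbl(seq_len(nrow(counts)), function(i) {
    test_fun(counts$reads_1[i], total_1 - counts$reads_1[i],
             counts$reads_2[i], total_2 - counts$reads_2[i])
  })
  padj <- bh_adjust(p)
  fold_ok <- !is.nan(fold) & (fold >= min_fold | fold <= 1 / min_fold)
  out <- tibble(
    gene_id = counts$gene_id,
    rpkm_1 = r1, rpkm_2 = r2,
    fold_change = fold,
    p_value = p, p_adjusted = padj,
    deg = padj < fdr & fold_ok
  )
  structure(list(results = out, total_1 = total_1, total_2 = total_2,
                 fdr = fdr, min_fold = min_fold),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat("<deg_result> ", nrow(x$results), " genes, ",
      sum(x$results$deg), " differentially expressed (FDR < ", x$fdr,
      ", fold >= ", x$min_fold, ")\n", sep = "")
  invisible(x)
}

#' @rdname deg_call
#' @param x,object A `deg_result`.
#' @param ... Unused.
#' @export
tidy.deg_result <- function(x, ...) x$results

#' @rdname deg_call
#' @export
glance.deg_result <- function(x, ...) {
  tibble(n_genes = nrow(x$results), n_deg = sum(x$results$deg),
         fdr = x$fdr, min_fold = x$min_fold,
         total_1 = x$total_1, total_2 = x$total_2)
}

#' @rdname deg_call
#' @export
autoplot.deg_result <- function(object, ...) {
  df <- mutate(object$results,
               mean_rpkm = (.data$rpkm_1 + .data$rpkm_2) / 2,
               log2fc = log2(.data$fold_change))
  ggplot(df, aes(x = .data$mean_rpkm, y = .data$log2fc,
                 colour = .data$deg)) +
    geom_point(alpha = 0.7) +
    scale_x_log10() +
    scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    labs(x = "mean RPKM", y = "log2 fold change (library 2 / library 1)",
         colour = "DEG") +
    theme_minimal()
}

#' Hypergeometric enrichment with Bonferroni adjustment
#'
#' Upper-tail hypergeometric test `P(X >= observed)` for over-
#' representation of an annotation among a drawn gene set, Bonferroni-
#' adjusted for the number of terms tested.
#'
#' @param n_drawn Size of the drawn gene set.
#' @param n_annotated_drawn Annotated genes within the drawn set.
#' @param n_population Background population size.
#' @param n_annotated_population Annotated genes in the population.
#' @param n_terms Number of annotation terms tested (Bonferroni factor).
#' @param alpha Significance level on the adjusted p (strict `<`).
#' @return A list with `p_value`, `p_adjusted`, `significant`.
#' @examples
#' hypergeom_enrich(2, 2, 10, 5, 1)$p_value  # C(5,2)/C(10,2) = 10/45
#' @export
hypergeom_enrich <- function(n_drawn, n_annotated_drawn, n_population,
                             n_annotated_population, n_terms = 1,
                             alpha = heat_config()$enrich$alpha) {
  if (n_drawn > n_population ||
      n_annotated_drawn > n_annotated_population ||
      n_annotated_drawn > n_drawn ||
      n_annotated_population > n_population) {
    abort("hypergeom_enrich: inconsistent counts")
  }
  p <- phyper(n_annotated_drawn - 1, n_annotated_population,
              n_population - n_annotated_population, n_drawn,
              lower.tail = FALSE)
  padj <- min(1, p * n_terms)
  list(p_value = p, p_adjusted = padj, significant = padj < alpha)
}

#' Livak fold change from cycle thresholds
#'
#' `2^-ddCT` relative expression of a target gene, normalized to a
#' reference gene and a control condition:
#' `ddCT = (CT_target,treated - CT_ref,treated) -
#'         (CT_target,control - CT_ref,control)`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Mean CT values (positive).
#' @return The fold change `2^-ddCT`.
#' @examples
#' ddct(20, 18, 22, 18)  # 4
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(cts <= 0)) abort("ddct: CT values must be positive")
  dd <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-dd)
}

#' Allele-specific primer efficiency coefficient
#'
#' Genomic DNA of a heterozygote carries the two alleles in equal
#' amounts, so any CT difference between the two allele-specific primers
#' on gDNA reflects unequal amplification efficiency. The coefficient is
#' defined as `2^-dCT` with `dCT = CT_allele1 - CT_allele2`; it equals 1
#' for equally efficient primers and rescales cDNA allele ratios via
#' [normalized_allele_ratio()].
#'
#' @param gdna_ct_allele1,gdna_ct_allele2 Mean gDNA CT per allele primer
#'   (same heterozygous individual).
#' @return The efficiency coefficient (> 0).
#' @examples
#' allele_efficiency_coeff(20, 20)  # 1
#' @export
allele_efficiency_coeff <- function(gdna_ct_allele1, gdna_ct_allele2) {
  if (any(c(gdna_ct_allele1, gdna_ct_allele2) <= 0)) {
    abort("allele_efficiency_coeff: CT values must be positive")
  }
  2^(-(gdna_ct_allele1 - gdna_ct_allele2))
}

#' Efficiency-normalized allelic expression ratio
#'
#' The raw cDNA allele ratio `2^-(CT1 - CT2)` divided by the gDNA
#' efficiency coefficient, giving the true allele-1 : allele-2
#' expression ratio.
#'
#' @param cdna_ct_allele1,cdna_ct_allele2 Mean cDNA CT per allele primer.
#' @param coefficient Efficiency coefficient from
#'   [allele_efficiency_coeff()] (> 0).
#' @return The normalized allele ratio.
#' @export
normalized_allele_ratio <- function(cdna_ct_allele1, cdna_ct_allele2,
                                    coefficient) {
  if (any(coefficient <= 0)) {
    abort("normalized_allele_ratio: coefficient must be positive")
  }
  2^(-(cdna_ct_allele1 - cdna_ct_allele2)) / coefficient
}

# internal: replicate-averaged CT per (sample, condition, template, primer)
mean_ct <- function(records) {
  records |>
    group_by(.data$sample_id, .data$condition, .data$template,
             .data$primer) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
}

#' Allele-specific expression analysis from a CT table
#'
#' Averages replicate CTs, derives the primer-efficiency coefficient
#' from the gDNA records of heterozygous samples, and reports the raw
#' and efficiency-normalized allele expression ratio per condition from
#' the cDNA records.
#'
#' @param records CT tibble (see [read_ct_table()]) with allele primers
#'   labelled `allele1` and `allele2`.
#' @param allele1,allele2 Primer labels of the two alleles.
#' @return A tibble per condition: `coefficient`, `raw_ratio`,
#'   `normalized_ratio` (allele-1 over allele-2).
#' @export
allele_expression_ratio <- function(records, allele1 = "allele1",
                                    allele2 = "allele2") {
  m <- mean_ct(records)
  gd <- filter(m, .data$template == "gDNA",
               .data$primer %in% c(allele1, allele2))
  if (nrow(gd) == 0) abort("allele_expression_ratio: no gDNA allele records")
  gd_wide <- pivot_wider(gd, names_from = "primer", values_from = "ct")
  coeff <- mean(allele_efficiency_coeff(gd_wide[[allele1]],
                                        gd_wide[[allele2]]))
  cd <- filter(m, .data$template == "cDNA",
               .data$primer %in% c(allele1, allele2))
  if (nrow(cd) == 0) abort("allele_expression_ratio: no cDNA allele records")
  cd |>
    pivot_wider(names_from = "primer", values_from = "ct") |>
    mutate(raw_ratio = 2^(-(.data[[allele1]] - .data[[allele2]]))) |>
    group_by(.data$condition) |>
    summarise(raw_ratio = mean(.data$raw_ratio), .groups = "drop") |>
    mutate(coefficient = coeff,
           normalized_ratio = .data$raw_ratio / coeff) |>
    select("condition", "coefficient", "raw_ratio", "normalized_ratio")
}

#' Target-gene expression fold change from a CT table
#'
#' Replicate-averages CTs and applies [ddct()] per sample pairing of the
#' target and reference primers, comparing a treated condition against a
#' control condition at the condition-mean level.
#'
#' @param records CT tibble (cDNA rows are used).
#' @param target,reference Primer labels.
#' @param treated,control Condition labels.
#' @return The `2^-ddCT` fold change (treated vs control).
#' @export
expression_fold <- function(records, target = "target",
                            reference = "reference",
                            treated = "heat", control = "control") {
  m <- filter(mean_ct(records), .data$template == "cDNA",
              .data$primer %in% c(target, reference))
  avg <- m |>
    group_by(.data$condition, .data$primer) |>
    summarise(ct = mean(.data$ct), .groups = "drop") |>
    pivot_wider(names_from = "primer", values_from = "ct")
  need <- c(treated, control)
  if (!all(need %in% avg$condition)) {
    abort(paste0("expression_fold: conditions not found: ",
                 paste(setdiff(need, avg$condition), collapse = ", ")))
  }
  tr <- avg[avg$condition == treated, ]
  co <- avg[avg$condition == control, ]
  ddct(tr[[target]], tr[[reference]], co[[target]], co[[reference]])
}
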