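# Readers and writers for the external formats the pipeline touches.
# All coordinates are 1-based and inclusive; TSVs are tab-separated UTF-8
# with '#' comment lines ignored.

#' Read unigene reference sequences from FASTA
#'
#' Sequences are uppercased on read; `N` is allowed. Duplicate ids are an
#' error (the unigene set is the SNP coordinate system and must be unique).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `unigene_id`, `sequence`, `length`.
#' @export
read_unigene_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate unigene id(s) in FASTA: ",
                 paste(unique(dup), collapse = ", ")))
  }
  seq_chr <- unname(toupper(as.character(seqs)))
  if (any(nchar(seq_chr) == 0)) abort("empty sequence in FASTA")
  hs_log("read_unigene_fasta: ", length(ids), " records from ", path)
  tibble(unigene_id = ids, sequence = unname(seq_chr),
         length = nchar(seq_chr))
}

#' Write unigene reference sequences to FASTA
#'
#' @param reference Tibble with `unigene_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unigene_fasta <- function(reference, path) {
  stopifnot(all(c("unigene_id", "sequence") %in% names(reference)))
  x <- Biostrings::DNAStringSet(reference$sequence)
  names(x) <- reference$unigene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# internal: shared readr spec for variant-call TSVs
variant_cols <- function() {
  cols(
    unigene_id = col_character(),
    pos = col_integer(),
    ref = col_character(),
    genotype = col_character(),
    score = col_double(),
    depth = col_integer(),
    depth_A = col_integer(),
    depth_C = col_integer(),
    depth_G = col_integer(),
    depth_T = col_integer()
  )
}

# internal: validate a variant-call tibble (shared by reader and simulator)
validate_variant_calls <- function(calls, source = "variant table") {
  need <- c("unigene_id", "pos", "ref", "genotype", "score", "depth",
            paste0("depth_", DNA_BASES))
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0(source, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(calls$pos < 1L)) {
    abort(paste0(source, ": position < 1 at row ",
                 which(calls$pos < 1L)[1]))
  }
  calls$genotype <- normalize_gt(calls$genotype)
  al <- gt_alleles(calls$genotype)
  bad_base <- !(al[, 1] %in% DNA_BASES) | !(al[, 2] %in% DNA_BASES)
  if (any(bad_base)) {
    abort(paste0(source, ": genotype with non-ACGT base at row ",
                 which(bad_base)[1], " (", calls$genotype[which(bad_base)[1]],
                 ")"))
  }
  if (any(!(calls$ref %in% DNA_BASES))) {
    abort(paste0(source, ": non-ACGT reference allele"))
  }
  if (any(calls$score < 0) || any(calls$depth < 0)) {
    abort(paste0(source, ": negative score or depth"))
  }
  ad_sum <- rowSums(as.matrix(calls[paste0("depth_", DNA_BASES)]))
  over <- !is.na(ad_sum) & ad_sum > calls$depth
  if (any(over)) {
    abort(paste0(source, ": allele depths sum (", ad_sum[which(over)[1]],
                 ") exceeds site depth (", calls$depth[which(over)[1]],
                 ") at row ", which(over)[1]))
  }
  calls
}

#' Read a per-population variant-call table
#'
#' Expects a tab-separated file with a header row naming the columns
#' `unigene_id`, `pos`, `ref`, `genotype`, `score`, `depth` and one
#' `depth_<base>` column per base (A, C, G, T), in the style of a
#' consensus-caller output. Rows are kept in file order. The genotype is
#' an unordered pair of bases written as a two-letter string (homozygote
#' = identical letters); it is normalized to sorted order on read.
#'
#' @param path Path to the TSV.
#' @return A tibble of validated variant calls.
#' @export
read_variant_calls <- function(path) {
  calls <- read_tsv(path, col_types = variant_cols(), comment = "#",
                    progress = FALSE)
  calls <- validate_variant_calls(calls, source = path)
  hs_log("read_variant_calls: ", nrow(calls), " calls from ", path)
  calls
}

#' Write a variant-call table
#'
#' @param calls A variant-call tibble.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(calls, path) {
  write_tsv(calls, path, progress = FALSE)
  invisible(path)
}

#' Construct a genotype matrix object
#'
#' A genotype matrix holds diploid calls for `individuals x SNPs`,
#' together with the two alleles declared per SNP. Calls are two-letter
#' strings over each SNP's declared alleles; missing calls are `NA`.
#'
#' @param calls Tibble with an `individual_id` column and one column per
#'   SNP containing normalized genotype strings or `NA`.
#' @param snps Tibble with columns `snp_id`, `a1`, `a2` (`NA` alleles are
#'   allowed for all-missing SNPs, which are flagged).
#' @return An object of class `geno_matrix`.
#' @export
genotype_matrix <- function(calls, snps) {
  stopifnot("individual_id" %in% names(calls))
  snp_cols <- setdiff(names(calls), "individual_id")
  if (!setequal(snp_cols, snps$snp_id)) {
    abort("genotype_matrix: call columns and snp table do not match")
  }
  if (anyDuplicated(calls$individual_id)) {
    abort("genotype_matrix: duplicate individual ids")
  }
  structure(
    list(calls = as_tibble(calls), snps = as_tibble(snps)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_all_missing <- sum(is.na(x$snps$a1))
  cat("<geno_matrix> ", nrow(x$calls), " individuals x ",
      nrow(x$snps), " SNPs", sep = "")
  if (n_all_missing > 0) cat(" (", n_all_missing, " all-missing)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$calls), nrow(x$snps))

#' Tidy a genotype matrix to long format
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `individual_id`, `snp_id`, `genotype`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  pivot_longer(x$calls, -"individual_id",
               names_to = "snp_id", values_to = "genotype")
}

#' Read a genotype matrix from TSV
#'
#' First column is the individual id; remaining columns hold two-letter
#' genotype strings or the missing code. The two alleles of each SNP are
#' inferred as the two bases observed in its column; a column with three
#' or more distinct bases is an error, and an all-missing column loads
#' with undeclared (`NA`) alleles and is flagged with a warning.
#'
#' @param path Path to the TSV.
#' @param missing_code Genotype string treated as missing (default `"NN"`).
#' @return A [genotype_matrix()] object.
#' @export
read_genotype_matrix <- function(path, missing_code = heat_config()$io$missing_code) {
  # readr flags short rows as parsing problems; raggedness is re-detected
  # below and reported as a structured error instead
  raw <- suppressWarnings(
    read_tsv(path, col_types = cols(.default = col_character()),
             comment = "#", progress = FALSE))
  if (ncol(raw) < 2) abort("genotype matrix needs an id column and >= 1 SNP column")
  if (anyNA(raw)) abort(paste0(path, ": ragged or incomplete rows"))
  names(raw)[1] <- "individual_id"
  snp_cols <- setdiff(names(raw), "individual_id")
  calls <- raw
  for (sc in snp_cols) {
    v <- calls[[sc]]
    v[v == missing_code] <- NA_character_
    calls[[sc]] <- normalize_gt(v)
  }
  snps <- purrr::map(snp_cols, function(sc) {
    obs <- calls[[sc]][!is.na(calls[[sc]])]
    bases <- sort(unique(as.vector(gt_alleles(obs))))
    if (length(bases) > 2) {
      abort(paste0(path, ": SNP column '", sc, "' contains ",
                   length(bases), " distinct bases (",
                   paste(bases, collapse = ","), "); at most 2 allowed"))
    }
    if (any(!bases %in% DNA_BASES)) {
      abort(paste0(path, ": SNP column '", sc, "' has non-ACGT base"))
    }
    tibble(snp_id = sc,
           a1 = if (length(bases) >= 1) bases[1] else NA_character_,
           a2 = if (length(bases) >= 2) bases[2] else bases[1] %||% NA_character_)
  }) |> bind_rows()
  # a monomorphic column keeps a1 == a2; an all-missing column keeps NA/NA
  all_missing <- snps$snp_id[is.na(snps$a1)]
  if (length(all_missing) > 0) {
    warn(paste0("all-missing SNP column(s), alleles undeclared: ",
                paste(all_missing, collapse = ", ")))
  }
  hs_log("read_genotype_matrix: ", nrow(calls), " individuals x ",
         length(snp_cols), " SNPs from ", path)
  genotype_matrix(calls, snps)
}

#' Write a genotype matrix to TSV
#'
#' @param gm A `geno_matrix`.
#' @param path Output path.
#' @param missing_code String written for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(gm, path,
                                  missing_code = heat_config()$io$missing_code) {
  out <- gm$calls
  for (sc in setdiff(names(out), "individual_id")) {
    v <- out[[sc]]
    v[is.na(v)] <- missing_code
    out[[sc]] <- v
  }
  write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a temperature schedule
#'
#' A schedule is a step function: each row gives a breakpoint time
#' (hours from stress start) and the temperature that holds from that
#' time until the next breakpoint. Times must be strictly increasing and
#' start at 0.
#'
#' @param path CSV with columns `time` (hours) and `temp` (degrees C).
#' @return A tibble with columns `time`, `temp`.
#' @export
read_temperature_schedule <- function(path) {
  sched <- read_csv(path, col_types = cols(time = col_double(),
                                           temp = col_double()),
                    progress = FALSE)
  validate_schedule(sched)
  sched
}

# internal
validate_schedule <- function(schedule) {
  stopifnot(all(c("time", "temp") %in% names(schedule)))
  if (nrow(schedule) == 0) abort("empty temperature schedule")
  if (schedule$time[1] != 0) abort("schedule must start at time 0")
  if (any(diff(schedule$time) <= 0)) abort("schedule times must be strictly increasing")
  if (any(!is.finite(schedule$temp))) abort("schedule temperatures must be finite")
  invisible(schedule)
}

#' Read death-time records
#'
#' @param path CSV with columns `individual_id`, `death_time` (hours) and
#'   optionally `censored` (logical; survivors at schedule end).
#' @return A tibble.
#' @export
read_death_times <- function(path) {
  d <- read_csv(path, col_types = cols(), progress = FALSE)
  stopifnot(all(c("individual_id", "death_time") %in% names(d)))
  if (!"censored" %in% names(d)) d$censored <- FALSE
  if (any(d$death_time < 0)) abort("negative death time")
  d
}

#' Read a qPCR CT table
#'
#' @param path CSV with columns `sample_id`, `condition`, `primer`,
#'   `template`, `replicate`, `ct`.
#' @return A tibble.
#' @export
read_ct_table <- function(path) {
  d <- read_csv(path, col_types = cols(), progress = FALSE)
  need <- c("sample_id", "condition", "primer", "template", "replicate", "ct")
  if (!all(need %in% names(d))) {
    abort(paste0(path, ": CT table needs columns ",
                 paste(need, collapse = ", ")))
  }
  if (any(d$ct <= 0)) abort("CT values must be positive")
  d
}

#' Read a gene annotation table
#'
#' @param path TSV mapping `unigene_id` to a free-text `description`
#'   (optional further columns such as GO/KEGG are carried through).
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  d <- read_tsv(path, col_types = cols(.default = col_character()),
                comment = "#", progress = FALSE)
  stopifnot(all(c("unigene_id", "description") %in% names(d)))
  d
}

#' Export classified SNPs as VCF v4.2
#'
#' Writes a minimal VCF with the unigene as CHROM, the classification
#' category in INFO, and the two pool genotypes as samples `north` and
#' `south`. Export only; the pipeline does not read VCF back.
#'
#' @param classified Output of [classify_snps()].
#' @param path Output path.
#' @param reference Optional reference tibble (adds contig header lines).
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(classified, path, reference = NULL) {
  cl <- filter(classified, !is.na(.data$category))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=heatsnp",
    '##INFO=<ID=CAT,Number=1,Type=String,Description="Cross-population SNP category">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(reference)) {
    hdr <- c(hdr, paste0("##contig=<ID=", reference$unigene_id,
                         ",length=", nchar(reference$sequence), ">"))
  }
  gt_vcf <- function(gt, ref, alt_all) {
    # map a two-letter genotype to VCF allele indices
    out <- character(length(gt))
    for (i in seq_along(gt)) {
      if (is.na(gt[i])) { out[i] <- "./."; next }
      al <- c(substr(gt[i], 1, 1), substr(gt[i], 2, 2))
      idx <- match(al, c(ref[i], strsplit(alt_all[i], ",")[[1]])) - 1L
      out[i] <- paste(idx, collapse = "/")
    }
    out
  }
  alt <- map_chr(seq_len(nrow(cl)), function(i) {
    al <- unique(c(gt_alleles(cl$north_gt[i]), gt_alleles(cl$south_gt[i])))
    al <- setdiff(al[!is.na(al)], cl$ref[i])
    if (length(al) == 0) "." else paste(sort(al), collapse = ",")
  })
  body <- paste(cl$unigene_id, cl$pos, cl$snp_id, cl$ref, alt, ".", "PASS",
                paste0("CAT=", cl$category), "GT",
                gt_vcf(cl$north_gt, cl$ref, alt),
                gt_vcf(cl$south_gt, cl$ref, alt),
                sep = "\t")
  col_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "north", "south"), collapse = "\t")
  writeLines(c(hdr, col_line, body), path)
  invisible(path)
}
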