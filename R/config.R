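#' Default pipeline thresholds
#'
#' Returns the full set of tunable thresholds used across the pipeline,
#' grouped by stage. Every value can be overridden either by passing a
#' modified copy to the stage functions or via a YAML config file read
#' with [read_heat_config()].
#'
#' The defaults are the published study conditions for this kind of
#' pooled-transcriptome candidate-gene analysis:
#'
#' * `quality`: keep a call iff genotype score >= 30, 10 < depth < 100,
#'   and (heterozygotes) minor-allele depth >= 4 with depth-based
#'   MAF >= 5%; reject when more than 5 SNPs fall in a 51-bp window.
#' * `imbalance`: a SNP is allelically imbalanced when the north/south
#'   pooled frequency ratio is >= 5 or <= 0.2 (inclusive).
#' * `hrm`: high-resolution-melting feasibility -- no second SNP within
#'   +/- 20 bp, no A/T or G/C transversion, and a 40-100 bp amplicon
#'   window must fit on the unigene.
#' * `qc`: association QC -- keep individuals with missing rate < 0.1,
#'   SNPs with missing rate < 0.5 and exact-HWE p > 0.001 (all strict).
#' * `deg`: differential expression -- BH-adjusted p < 0.01 and at least
#'   two-fold RPKM change.
#' * `phenotype`: baseline (acclimation) temperature 25 degrees C for
#'   degree-hour accumulation; extreme-group size k = 48.
#'
#' @return A named list of lists of thresholds.
#' @examples
#' heat_config()$quality$min_genotype_score
#' @export
heat_config <- function() {
  list(
    quality = list(
      min_genotype_score = 30,
      depth_low = 10,
      depth_high = 100,
      min_minor_depth = 4,
      min_maf = 0.05,
      density_window_bp = 50,
      density_max_snps = 5
    ),
    imbalance = list(
      high = 5,
      low = 0.2,
      restrict_to_shared = TRUE
    ),
    hrm = list(
      flank_bp = 20,
      amplicon_min = 40,
      amplicon_max = 100
    ),
    qc = list(
      max_missing_per_snp = 0.5,
      max_missing_per_individual = 0.1,
      min_hwe_p = 0.001
    ),
    deg = list(
      fdr = 0.01,
      min_fold = 2
    ),
    enrich = list(
      alpha = 0.01
    ),
    phenotype = list(
      baseline_temp = 25,
      k_extremes = 48
    ),
    io = list(
      missing_code = "NN"
    )
  )
}

#' Read a pipeline config file
#'
#' Reads a YAML key-value file and merges it recursively over the
#' defaults from [heat_config()]; keys absent from the file keep their
#' default value. Unknown top-level keys raise an error so typos do not
#' silently leave a threshold at its default.
#'
#' @param path Path to a YAML file.
#' @return A config list with the same structure as [heat_config()].
#' @export
read_heat_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  base <- heat_config()
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown config section(s): ", paste(unknown, collapse = ", ")))
  }
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(bad) > 0) {
      abort(paste0("unknown key(s) in config section '", sec, "': ",
                   paste(bad, collapse = ", ")))
    }
    base[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  base
}
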