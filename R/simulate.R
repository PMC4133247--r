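# Synthetic-data generators. Every input the pipeline consumes can be
# simulated with known ground truth: a unigene reference, pooled variant
# calls from two diverged subspecies pools, heat-stressed cohorts with a
# planted effect SNP, and qPCR CT tables with allele-specific
# amplification efficiencies. All generators are deterministic for a
# fixed seed and restore the caller's RNG state; multi-stage simulations
# derive stage seeds from one master seed as seed, seed + 1, seed + 2, ...

# internal: scoped seeding that restores the caller's RNG state
hs_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

hs_restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a unigene reference
#'
#' Independent uniform-base sequences. Lengths below 100 bp are refused
#' so that flanking-window filters always have room to operate.
#'
#' @param n_unigenes Number of unigenes (>= 1).
#' @param length_range Length-2 integer vector of min/max length (>= 100).
#' @param seed RNG seed.
#' @return A reference tibble as from [read_unigene_fasta()].
#' @export
sim_reference <- function(n_unigenes, length_range = c(200, 2000), seed = 1) {
  if (n_unigenes < 1) abort("sim_reference: n_unigenes must be >= 1")
  if (min(length_range) < 100) {
    abort("sim_reference: unigene lengths must be >= 100 bp")
  }
  old <- hs_seed(seed)
  on.exit(hs_restore_seed(old), add = TRUE)
  len_choices <- seq(length_range[1], length_range[2])
  lens <- len_choices[sample.int(length(len_choices), n_unigenes,
                                 replace = TRUE)]
  seqs <- map_chr(lens, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  })
  tibble(
    unigene_id = sprintf("sim-%05d", seq_len(n_unigenes)),
    sequence = seqs,
    length = lens
  )
}

# internal: positions for planted SNPs on a reference, keeping singles
# >= min_gap apart (so they never trip the density rule by accident)
allocate_positions <- function(reference, n, min_gap = 51, margin = 25,
                               occupied = NULL) {
  occupied <- occupied %||% list()
  out <- vector("list", n)
  w <- reference$length - 2 * margin
  w[w < 1] <- 0
  if (all(w == 0)) abort("allocate_positions: reference too short")
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:100) {
      ug_i <- sample.int(nrow(reference), 1, prob = w)
      ug <- reference$unigene_id[ug_i]
      pos <- sample.int(reference$length[ug_i] - 2 * margin, 1) + margin
      occ <- occupied[[ug]] %||% integer(0)
      if (length(occ) == 0 || min(abs(occ - pos)) >= min_gap) {
        occupied[[ug]] <- c(occ, pos)
        out[[i]] <- tibble(unigene_id = ug, pos = pos)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("allocate_positions: could not place a SNP in 100 tries; reference too dense")
    }
  }
  list(sites = bind_rows(out), occupied = occupied)
}

# internal: clipped negative-binomial site depths
sim_depth <- function(n, mean, size, max_depth) {
  pmin(pmax(rnbinom(n, mu = mean, size = size), 1L), max_depth)
}

# internal: build one pool's call row for a planted site
build_call <- function(unigene_id, pos, ref, gt, depth, score, f_alt) {
  al <- c(substr(gt, 1, 1), substr(gt, 2, 2))
  ad <- setNames(rep(0L, 4), DNA_BASES)
  if (al[1] == al[2]) {
    ad[al[1]] <- depth
  } else {
    alt <- setdiff(al, ref)
    alt <- if (length(alt) == 0) al[2] else alt[1]
    other <- setdiff(al, alt)[1]
    k <- rbinom(1, depth, f_alt)
    ad[alt] <- k
    ad[other] <- depth - k
  }
  tibble(unigene_id = unigene_id, pos = pos, ref = ref, genotype = gt,
         score = score, depth = as.integer(depth),
         depth_A = unname(ad["A"]), depth_C = unname(ad["C"]),
         depth_G = unname(ad["G"]), depth_T = unname(ad["T"]))
}

#' Simulate pooled variant calls for two subspecies pools
#'
#' Plants SNPs of each cross-population category on a reference and
#' emits the per-pool call tables a consensus caller would produce
#' (a pool that matches the reference at a site emits no call there).
#' Planted genotypes obey their category's pattern exactly, so
#' classification at zero noise recovers the planted categories;
#' per-site depths and heterozygous allele depths are drawn from a
#' clipped negative binomial and a binomial around the true pool
#' frequency, so depth-filter tails and allele-frequency noise occur at
#' realistic rates. A configurable fraction of the `violate_pool`'s
#' specific SNPs is forced to violate each quality rule, and
#' `n_density_clusters` clusters of six tightly spaced SNPs exercise the
#' density rule.
#'
#' @param reference Reference tibble ([sim_reference()] or
#'   [read_unigene_fasta()]).
#' @param category_rates Named integer vector: number of SNPs to plant
#'   per category (`inter`, `shared`, `north`, `south`).
#' @param shared_diff_frac Fraction of shared SNPs with different
#'   heterozygosity type in the two pools.
#' @param hom_frac Fraction of pool-specific SNPs homozygous (rather
#'   than heterozygous) for the derived allele.
#' @param depth_mean,depth_size,depth_max Negative-binomial depth model
#'   (mean 40, clipped to `[1, 150]`: both depth-filter tails occur).
#' @param score_mean,score_sd Genotype-score model (normal, floored at
#'   the default score threshold so clean calls pass rule (a)).
#' @param violate_frac Named fractions of the violate-pool's specific
#'   SNPs forced to fail each rule: `score`, `depth`, `minor`.
#' @param n_density_clusters Number of 6-SNP clusters (each within one
#'   50-bp window).
#' @param violate_pool Which pool carries the forced violators.
#' @param seed RNG seed.
#' @return A list with `north` and `south` call tibbles and `truth`
#'   (per-SNP tibble: category, genotypes, true focal-allele pool
#'   frequencies, forced violation; the seed is attached as an
#'   attribute).
#' @export
sim_pooled_calls <- function(reference,
                             category_rates = c(inter = 30, shared = 30,
                                                north = 30, south = 30),
                             shared_diff_frac = 0.15,
                             hom_frac = 0.3,
                             depth_mean = 40, depth_size = 6,
                             depth_max = 150,
                             score_mean = 60, score_sd = 15,
                             violate_frac = c(score = 0.05, depth = 0.05,
                                              minor = 0.05),
                             n_density_clusters = 1,
                             violate_pool = "north",
                             seed = 1) {
  stopifnot(all(c("inter", "shared", "north", "south") %in%
                  names(category_rates)))
  if (any(category_rates < 0)) abort("sim_pooled_calls: negative category rate")
  old <- hs_seed(seed)
  on.exit(hs_restore_seed(old), add = TRUE)

  n_single <- sum(category_rates)
  cats <- rep(c("inter", "shared", "north", "south"),
              times = category_rates[c("inter", "shared", "north", "south")])
  truth_rows <- list()
  north_rows <- list()
  south_rows <- list()
  occupied <- list()

  if (n_single > 0) {
    alloc <- allocate_positions(reference, n_single, occupied = occupied)
    occupied <- alloc$occupied
    sites <- alloc$sites
    ref_base <- map_chr(seq_len(n_single), function(i) {
      substr(reference$sequence[reference$unigene_id == sites$unigene_id[i]],
             sites$pos[i], sites$pos[i])
    })
    for (i in seq_len(n_single)) {
      r <- ref_base[i]
      non_ref <- setdiff(DNA_BASES, r)
      cat_i <- cats[i]
      if (cat_i == "inter") {
        xy <- sample(non_ref, 2)
        ngt <- paste0(xy[1], xy[1])
        sgt <- paste0(xy[2], xy[2])
        focal <- min(xy)
        f_n <- as.numeric(focal == xy[1])
        f_s <- as.numeric(focal == xy[2])
      } else if (cat_i == "shared") {
        if (runif(1) < shared_diff_frac) {
          xy <- sample(non_ref, 2)
          ngt <- normalize_gt(paste0(r, xy[1]))
          sgt <- normalize_gt(paste0(r, xy[2]))
          focal <- min(xy)
          f_n <- 0.5 * (focal == xy[1])
          f_s <- 0.5 * (focal == xy[2])
        } else {
          a <- sample(non_ref, 1)
          ngt <- sgt <- normalize_gt(paste0(r, a))
          focal <- a
          f_n <- f_s <- 0.5
        }
      } else {
        a <- sample(non_ref, 1)
        gt <- if (runif(1) < hom_frac) paste0(a, a) else
          normalize_gt(paste0(r, a))
        focal <- a
        f_self <- if (gt == paste0(a, a)) 1 else 0.5
        if (cat_i == "north") {
          ngt <- gt; sgt <- NA_character_
          f_n <- f_self; f_s <- 0
        } else {
          sgt <- gt; ngt <- NA_character_
          f_s <- f_self; f_n <- 0
        }
      }
      truth_rows[[i]] <- tibble(
        unigene_id = sites$unigene_id[i], pos = sites$pos[i],
        snp_id = snp_id(sites$unigene_id[i], sites$pos[i]),
        category = if (cat_i == "shared") {
          if (ngt == sgt) "shared_same_het" else "shared_diff_het"
        } else if (cat_i == "inter") "inter_subspecific" else
          paste0(cat_i, "_specific"),
        ref = r, north_gt = ngt, south_gt = sgt,
        focal = focal, f_north = f_n, f_south = f_s,
        forced_violation = "none"
      )
    }
  }

  # density-rule violators: clusters of 6 SNPs inside one 50-bp window,
  # planted as violate-pool-specific heterozygotes
  if (n_density_clusters > 0) {
    long_enough <- reference[reference$length >= 200, , drop = FALSE]
    if (nrow(long_enough) == 0) abort("sim_pooled_calls: no unigene >= 200 bp for clusters")
    for (cl in seq_len(n_density_clusters)) {
      placed <- FALSE
      for (try in 1:100) {
        ug_i <- sample.int(nrow(long_enough), 1)
        ug <- long_enough$unigene_id[ug_i]
        len <- long_enough$length[ug_i]
        centre <- sample(76:(len - 75), 1)
        # all six sites pairwise within 25 bp, so each one's 51-bp window
        # holds all six and the whole cluster fails the density rule
        ps <- sort(centre + sample(-12:12, 6))
        occ <- occupied[[ug]] %||% integer(0)
        if (length(occ) == 0 || min(abs(outer(occ, ps, "-"))) >= 51) {
          occupied[[ug]] <- c(occ, ps)
          for (p in ps) {
            r <- substr(long_enough$sequence[ug_i], p, p)
            a <- sample(setdiff(DNA_BASES, r), 1)
            gt <- normalize_gt(paste0(r, a))
            row <- tibble(
              unigene_id = ug, pos = p, snp_id = snp_id(ug, p),
              category = paste0(violate_pool, "_specific"),
              ref = r,
              north_gt = if (violate_pool == "north") gt else NA_character_,
              south_gt = if (violate_pool == "south") gt else NA_character_,
              focal = a,
              f_north = if (violate_pool == "north") 0.5 else 0,
              f_south = if (violate_pool == "south") 0.5 else 0,
              forced_violation = "density"
            )
            truth_rows[[length(truth_rows) + 1]] <- row
          }
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("sim_pooled_calls: could not place a density cluster in 100 tries")
    }
  }

  truth <- bind_rows(truth_rows)
  if (nrow(truth) == 0) {
    empty <- validate_variant_calls(
      tibble(unigene_id = character(), pos = integer(), ref = character(),
             genotype = character(), score = double(), depth = integer(),
             depth_A = integer(), depth_C = integer(), depth_G = integer(),
             depth_T = integer()))
    attr(truth, "seed") <- seed
    return(list(north = empty, south = empty, truth = truth))
  }

  # forced single-rule violators among the violate pool's clean specific SNPs
  gt_col <- paste0(violate_pool, "_gt")
  specific <- which(truth$category == paste0(violate_pool, "_specific") &
                      truth$forced_violation == "none")
  pool_avail <- specific
  safe_sample <- function(x, n) x[sample.int(length(x), min(n, length(x)))]
  for (rule in c("score", "depth", "minor")) {
    frac <- violate_frac[[rule]] %||% 0
    n_v <- round(frac * length(specific))
    if (rule == "minor") {
      het_avail <- pool_avail[substr(truth[[gt_col]][pool_avail], 1, 1) !=
                                substr(truth[[gt_col]][pool_avail], 2, 2)]
      pick <- safe_sample(het_avail, n_v)
    } else {
      pick <- safe_sample(pool_avail, n_v)
    }
    truth$forced_violation[pick] <- rule
    pool_avail <- setdiff(pool_avail, pick)
  }

  # emit call rows
  for (i in seq_len(nrow(truth))) {
    for (side in c("north", "south")) {
      gt <- truth[[paste0(side, "_gt")]][i]
      if (is.na(gt)) next
      viol <- if (side == violate_pool) truth$forced_violation[i] else "none"
      depth <- sim_depth(1, depth_mean, depth_size, depth_max)
      if (viol == "depth") {
        depth <- if (runif(1) < 0.5) sample(1:10, 1) else sample(100:150, 1)
      }
      score <- if (viol == "score") runif(1, 0, 29.5) else
        pmax(30, rnorm(1, score_mean, score_sd))
      f_alt_pool <- if (side == "north") truth$f_north[i] else truth$f_south[i]
      # within-genotype alt fraction: hets sample reads around 0.5
      f_draw <- if (substr(gt, 1, 1) == substr(gt, 2, 2)) 1 else 0.5
      row <- build_call(truth$unigene_id[i], truth$pos[i], truth$ref[i],
                        gt, depth, score, f_draw)
      if (viol == "minor") {
        # force the minor-allele depth below the rule-(c) threshold
        al <- c(substr(gt, 1, 1), substr(gt, 2, 2))
        alt <- setdiff(al, truth$ref[i])[1]
        other <- setdiff(al, alt)[1]
        depth <- max(depth, 20L)
        row$depth <- as.integer(depth)
        minor_d <- sample(1:3, 1)
        row[[paste0("depth_", alt)]] <- minor_d
        row[[paste0("depth_", other)]] <- as.integer(depth - minor_d)
      }
      if (side == "north") north_rows[[length(north_rows) + 1]] <- row
      else south_rows[[length(south_rows) + 1]] <- row
    }
  }
  mk <- function(rows) {
    if (length(rows) == 0) {
      tibble(unigene_id = character(), pos = integer(), ref = character(),
             genotype = character(), score = double(), depth = integer(),
             depth_A = integer(), depth_C = integer(), depth_G = integer(),
             depth_T = integer())
    } else {
      arrange(bind_rows(rows), .data$unigene_id, .data$pos)
    }
  }
  truth <- arrange(truth, .data$unigene_id, .data$pos)
  attr(truth, "seed") <- seed
  list(north = mk(north_rows), south = mk(south_rows), truth = truth)
}

#' Default chronic heat-stress ramp
#'
#' A stepped temperature schedule starting at `start_temp` and raised by
#' `step_per_day` each day, the standard chronic heat-stress design for
#' marine invertebrate tolerance assays.
#'
#' @param start_temp Starting temperature, degrees C.
#' @param step_per_day Daily increment, degrees C.
#' @param days Number of days.
#' @return A schedule tibble (`time` in hours, `temp`).
#' @export
ramp_schedule <- function(start_temp = 26, step_per_day = 0.5, days = 40) {
  tibble(time = 24 * (seq_len(days) - 1),
         temp = start_temp + step_per_day * (seq_len(days) - 1))
}

#' Simulate a heat-stressed cohort with a planted effect SNP
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium at each panel
#' SNP's allele frequency. Death times follow an exponential baseline
#' hazard scaled per copy of the effect SNP's risk allele by
#' `odds_ratio` (so carriers die earlier and are enriched in the
#' heat-susceptible extreme); all other SNPs are independent of the
#' phenotype. Individuals alive at the end of the schedule are censored
#' there.
#'
#' @param n_individuals Cohort size (>= 4).
#' @param snp_panel Tibble with `snp_id`, `a1` (risk allele), `a2`,
#'   `maf` (frequency of `a1`); `NULL` builds a default panel of
#'   `n_snps` SNPs with the effect SNP at `maf` and the rest at
#'   frequencies drawn uniformly in `[0.1, 0.5]`.
#' @param effect_snp Id of the effect SNP (must be in the panel); `NULL`
#'   takes the panel's first SNP.
#' @param odds_ratio Per-risk-allele hazard scaling (> 0; 1 = no
#'   effect).
#' @param schedule Temperature schedule.
#' @param maf Effect-SNP risk-allele frequency for the default panel.
#' @param n_snps Default panel size.
#' @param base_rate Baseline death hazard per hour.
#' @param missing_rate Per-call genotype missingness.
#' @param baseline Baseline temperature for degree-hours.
#' @param seed RNG seed.
#' @return A list with `genotypes` (a [genotype_matrix()]),
#'   `phenotypes` (tibble: `individual_id`, `death_time`, `censored`,
#'   `degree_hours`) and `truth`.
#' @export
sim_cohort <- function(n_individuals, snp_panel = NULL, effect_snp = NULL,
                       odds_ratio = 1, schedule = ramp_schedule(),
                       maf = 0.3, n_snps = 20, base_rate = 1 / 300,
                       missing_rate = 0, baseline = 25, seed = 1) {
  if (n_individuals < 4) abort("sim_cohort: need at least 4 individuals")
  if (odds_ratio <= 0) abort("sim_cohort: odds_ratio must be positive")
  validate_schedule(schedule)
  old <- hs_seed(seed)
  on.exit(hs_restore_seed(old), add = TRUE)

  if (is.null(snp_panel)) {
    pairs <- replicate(n_snps, sample(DNA_BASES, 2), simplify = FALSE)
    snp_panel <- tibble(
      snp_id = sprintf("sim-%03d-%d", seq_len(n_snps),
                       sample(100:999, n_snps, replace = TRUE)),
      a1 = map_chr(pairs, 1),
      a2 = map_chr(pairs, 2),
      maf = c(maf, runif(n_snps - 1, 0.1, 0.5))
    )
  }
  stopifnot(all(c("snp_id", "a1", "a2", "maf") %in% names(snp_panel)))
  effect_snp <- effect_snp %||% snp_panel$snp_id[1]
  if (!effect_snp %in% snp_panel$snp_id) {
    abort("sim_cohort: effect_snp not in the panel")
  }

  ids <- sprintf("ind-%03d", seq_len(n_individuals))
  dosage <- matrix(0L, n_individuals, nrow(snp_panel))
  calls <- tibble(individual_id = ids)
  for (j in seq_len(nrow(snp_panel))) {
    g <- rbinom(n_individuals, 2, snp_panel$maf[j])
    dosage[, j] <- g
    gt <- map_chr(g, function(k) {
      normalize_gt(paste0(strrep(snp_panel$a1[j], k),
                          strrep(snp_panel$a2[j], 2 - k)))
    })
    if (missing_rate > 0) {
      gt[runif(n_individuals) < missing_rate] <- NA_character_
    }
    calls[[snp_panel$snp_id[j]]] <- gt
  }
  snps <- tibble(
    snp_id = snp_panel$snp_id,
    a1 = pmin(snp_panel$a1, snp_panel$a2),
    a2 = pmax(snp_panel$a1, snp_panel$a2)
  )
  gm <- genotype_matrix(calls, snps)

  eff_j <- match(effect_snp, snp_panel$snp_id)
  rate <- base_rate * odds_ratio^dosage[, eff_j]
  t_death <- rexp(n_individuals, rate)
  t_end <- schedule$time[nrow(schedule)]
  censored <- t_death > t_end
  deaths <- tibble(
    individual_id = ids,
    death_time = pmin(t_death, t_end),
    censored = censored
  )
  pheno <- add_degree_hours(deaths, schedule, baseline = baseline)
  truth <- list(effect_snp = effect_snp, risk_allele = snp_panel$a1[eff_j],
                odds_ratio = odds_ratio, maf = snp_panel$maf[eff_j],
                panel = snp_panel, seed = seed)
  list(genotypes = gm, phenotypes = pheno, truth = truth)
}

#' Simulate an allele-specific qPCR CT table
#'
#' Generates replicate CT measurements for target/reference primers
#' (both conditions) and, for heterozygous samples, the two
#' allele-specific primers on both genomic DNA and cDNA templates. On
#' gDNA the two alleles are equimolar, so their CTs differ only by the
#' primer-efficiency term `-log2(efficiency_coeff)`; on cDNA the CT
#' difference additionally encodes the true `allele_ratio`, and heat
#' samples encode `expression_fold`. With `noise_sd = 0` the
#' downstream efficiency coefficient, normalized allele ratio and
#' delta-delta-CT fold are recovered exactly.
#'
#' @param genotypes Tibble with `sample_id`, `genotype` (two-letter
#'   string over `alleles`), `condition` (`"control"`/`"heat"`);
#'   `NULL` builds a small default of two heterozygotes and two
#'   homozygotes per condition.
#' @param base_ct Reference CT level.
#' @param allele_ratio True allele-1 : allele-2 expression ratio (> 0).
#' @param efficiency_coeff True allele-primer efficiency coefficient
#'   (> 0).
#' @param expression_fold True heat / control target expression fold.
#' @param noise_sd Gaussian CT noise (>= 0).
#' @param n_replicates Technical replicates per measurement.
#' @param alleles The two alleles; `alleles[1]` is allele 1.
#' @param seed RNG seed.
#' @return A CT tibble (see [read_ct_table()]) with the simulation truth
#'   attached as attribute `"truth"`.
#' @export
sim_qpcr <- function(genotypes = NULL, base_ct = 20, allele_ratio = 1,
                     efficiency_coeff = 1, expression_fold = 1,
                     noise_sd = 0, n_replicates = 3,
                     alleles = c("T", "C"), seed = 1) {
  if (allele_ratio <= 0) abort("sim_qpcr: allele_ratio must be positive")
  if (efficiency_coeff <= 0) abort("sim_qpcr: efficiency_coeff must be positive")
  if (noise_sd < 0) abort("sim_qpcr: noise_sd must be non-negative")
  old <- hs_seed(seed)
  on.exit(hs_restore_seed(old), add = TRUE)
  if (is.null(genotypes)) {
    het <- normalize_gt(paste0(alleles[1], alleles[2]))
    hom <- paste0(alleles[1], alleles[1])
    genotypes <- tibble(
      sample_id = sprintf("s%02d", 1:8),
      genotype = rep(c(het, het, hom, hom), 2),
      condition = rep(c("control", "heat"), each = 4)
    )
  }
  stopifnot(all(c("sample_id", "genotype", "condition") %in% names(genotypes)))
  het_gt <- normalize_gt(paste0(alleles[1], alleles[2]))
  rows <- list()
  emit <- function(sample_id, condition, primer, template, ct) {
    rows[[length(rows) + 1]] <<- tibble(
      sample_id = sample_id, condition = condition, primer = primer,
      template = template, replicate = seq_len(n_replicates),
      ct = ct + if (noise_sd > 0) rnorm(n_replicates, 0, noise_sd) else 0
    )
  }
  for (i in seq_len(nrow(genotypes))) {
    sid <- genotypes$sample_id[i]
    cond <- genotypes$condition[i]
    expr <- if (cond == "heat") expression_fold else 1
    emit(sid, cond, "reference", "cDNA", base_ct)
    emit(sid, cond, "target", "cDNA", base_ct - log2(expr))
    if (normalize_gt(genotypes$genotype[i]) == het_gt) {
      # gDNA: equimolar alleles; CT difference is the efficiency term only
      emit(sid, cond, "allele2", "gDNA", base_ct)
      emit(sid, cond, "allele1", "gDNA", base_ct - log2(efficiency_coeff))
      # cDNA: the measured (raw) ratio compounds truth and efficiency
      ct2 <- base_ct - log2(expr)
      emit(sid, cond, "allele2", "cDNA", ct2)
      emit(sid, cond, "allele1", "cDNA",
           ct2 - log2(allele_ratio * efficiency_coeff))
    }
  }
  out <- bind_rows(rows)
  attr(out, "truth") <- list(allele_ratio = allele_ratio,
                             efficiency_coeff = efficiency_coeff,
                             expression_fold = expression_fold,
                             alleles = alleles, seed = seed)
  out
}
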