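# Independent oracles used across the suite. Each one recomputes a
# quantity by a different route than the package implementation:
# explicit choose()-based enumeration for the exact tests, brute-force
# O(n^2) window counting for the density rule, fine-grid quadrature for
# degree-hours, and a literal restatement of the classification rules.

# Two-sided Fisher exact p by full enumeration over the support, with
# point probabilities as normalized products of binomial coefficients.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; K <- a + c
  x <- max(0, K - n2):min(K, m)
  pr <- choose(m, x) * choose(n2, K - x)
  pr <- pr / sum(pr)
  p_obs <- pr[match(a, x)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Exact HWE p by enumeration of every heterozygote count compatible with
# the allele counts; probabilities composed from choose() and powers of 2.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  h <- seq(rare %% 2, rare, by = 2)
  n_homa <- (n_a - h) / 2
  pr <- choose(n, n_homa) * choose(n - n_homa, h) * 2^h / choose(2 * n, n_a)
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_ab, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Brute-force windowed SNP count: for each call, count calls on the same
# unigene within +/- hw bp by a double loop.
density_oracle <- function(unigene, pos, hw = 25) {
  n <- length(pos)
  counts <- integer(n)
  for (i in seq_len(n)) {
    counts[i] <- sum(unigene == unigene[i] & abs(pos - pos[i]) <= hw)
  }
  counts
}

# Degree-hours by midpoint quadrature on a fine grid whose knots include
# every schedule breakpoint (so the step function is constant on each cell).
degree_hours_oracle <- function(schedule, death_time, baseline = 25,
                                dt = 0.05) {
  if (death_time == 0) return(0)
  sf <- stats::stepfun(schedule$time[-1], schedule$temp)
  knots <- sort(unique(c(schedule$time[schedule$time < death_time],
                         death_time, 0)))
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    a <- knots[i]; b <- knots[i + 1]
    k <- max(1L, ceiling((b - a) / dt))
    mids <- a + (seq_len(k) - 0.5) * (b - a) / k
    total <- total + sum(pmax(sf(mids) - baseline, 0)) * (b - a) / k
  }
  total
}

# Literal restatement of the cross-population classification rules,
# written over allele sets rather than the package's vectorized strings.
# Absent pools are resolved to hom-reference before the call.
classify_oracle <- function(ref, north_gt, south_gt) {
  n <- sort(c(substr(north_gt, 1, 1), substr(north_gt, 2, 2)))
  s <- sort(c(substr(south_gt, 1, 1), substr(south_gt, 2, 2)))
  n_het <- n[1] != n[2]
  s_het <- s[1] != s[2]
  if (!n_het && !s_het) {
    if (n[1] == ref && s[1] == ref) return(NA_character_)
    if (n[1] != ref && s[1] == ref) return("north_specific")
    if (n[1] == ref && s[1] != ref) return("south_specific")
    if (n[1] != s[1]) return("inter_subspecific")
    return(NA_character_)  # both hom same non-ref allele
  }
  if (n_het && s_het) {
    if (identical(n, s)) return("shared_same_het")
    return("shared_diff_het")
  }
  if (n_het) return("north_specific")
  "south_specific"
}

# All diploid genotypes over ACGT as normalized strings
all_genotypes <- function() {
  g <- outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)
  unique(heatsnp:::normalize_gt(as.vector(g)))
}

# HRM amplicon-window feasibility by explicit enumeration of every
# (start, length) window.
amplicon_oracle <- function(pos, len, amp_min = 40, amp_max = 100) {
  for (L in amp_min:amp_max) {
    if (L > len) next
    for (s in 1:(len - L + 1)) {
      if (s <= pos && pos <= s + L - 1) return(TRUE)
    }
  }
  FALSE
}

# small convenience: a fixed three-column schedule for phenotype tests
toy_schedule <- function() {
  tibble::tibble(time = c(0, 24, 48), temp = c(26, 26.5, 27))
}
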