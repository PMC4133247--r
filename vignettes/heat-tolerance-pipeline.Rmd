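---
title: "From pooled-transcriptome variant calls to heat-tolerance candidate SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pooled-transcriptome variant calls to heat-tolerance candidate SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatsnp)
library(dplyr)
```

## The problem this package addresses

Two diverged subspecies of an aquaculture mollusc — a northern and a
southern bay scallop — differ in heat tolerance. A cost-effective route
to the loci involved is: sequence pooled RNA from many individuals of
each subspecies, call SNPs against a common unigene (assembled
transcript) reference, and use the cross-population patterns of those
SNPs, together with functional annotation, to nominate candidate genes;
then genotype candidate SNPs in heat-stressed intercross cohorts and
test allele frequencies between extreme-phenotype groups. `heatsnp`
implements every computational stage of that chain on plain tables, and
ships generators that simulate all of its inputs with known ground
truth.

## Variant-call filtering

A consensus caller applied to pooled reads emits one row per variant
site per pool: position on the unigene, reference base, diploid
consensus genotype, a genotype quality score, the site depth, and
per-base read depths. Four rules discard unreliable calls
(`filter_quality()`, `filter_density()`):

* genotype score < 30 (rule a);
* site depth ≤ 10 or ≥ 100 (rule b) — too shallow to trust, or likely
  collapsed paralogs;
* for heterozygous calls, minor-allele read depth < 4 or depth-based
  minor allele frequency < 5% (rule c) — in pooled data there are no
  per-individual genotypes, so MAF is necessarily estimated from read
  depths (minor depth / total allele depth at the site);
* more than 5 SNPs within the adjacent 50 bp (rule d) — a hallmark of
  misassembly or paralog collapse.

Two choices here were genuinely open and are fixed as follows. The
50 bp adjacency window is interpreted as a closed, symmetric 51-bp
window centred on the focal SNP (±25 bp): symmetric placement is
order-independent, and any asymmetric convention would make the rule
depend on scan direction. Second, the density rule is applied in a
single pass to the post-quality-filter call set: removals do not
trigger re-counting, because cascaded removal is a different (and
ill-specified) rule; idempotence on clean output is asserted by test.
Rules are *evaluated* in the fixed order a → d purely so the rejection
ledger can name one offending rule per call; membership of the kept set
does not depend on that order.

## Cross-population classification

Each site called in at least one pool is compared with the reference
base and the other pool's genotype (`classify_snps()`), yielding:
inter-subspecific (both pools homozygous for different non-reference
alleles), shared with the same or with a different heterozygosity type,
or specific to one pool. Two conventions matter:

* **Absent calls.** A consensus caller only reports sites that differ
  from the reference, so a pool with no call at a classified site is
  treated as homozygous-reference (`absent_as_ref = TRUE`); a strict
  mode instead skips such sites.
* **Combinations outside the four-way scheme.** A heterozygous pool
  facing a homozygous *non-reference* pool is assigned to the category
  of the segregating (heterozygous) pool and sub-flagged
  `het_vs_hom_nonref`. Both pools homozygous for the *same*
  non-reference allele is no between-pool SNP at all; it is returned
  with category `NA` and note `monomorphic_nonref` rather than forced
  into a category. Tri-allelic double-heterozygote sites fall in the
  "different heterozygosity type" shared class.

The classification is checked exhaustively: a test enumerates all
4 × 11 × 11 combinations of reference base and pool genotypes
(absence included) against an independently written restatement of the
rules, and asserts the north/south swap symmetry.

## Allelic imbalance

For SNPs observed in both pools, the pooled frequency of the focal
(non-reference) allele is estimated per pool from read depths, and the
imbalance score is the north/south frequency ratio. A SNP is
*imbalanced* when the score is ≥ 5 or ≤ 0.2, both inclusive; because
the two thresholds are reciprocal, the flag does not depend on which
allele of a biallelic site is scored. A pool with focal frequency zero
gives an infinite (imbalanced) score; sites with zero focal frequency
in both pools are undefined and skipped. By default scoring is
restricted to shared-category SNPs — for pool-specific SNPs the ratio
is structurally 0 or ∞ and carries no information beyond the category
itself — and sites below the quality filter's lower depth bound are
skipped to avoid ratio noise from tiny denominators.

## Candidate genes and HRM feasibility

Candidate genes are the union of (i) unigenes whose annotation matches
configurable keyword groups for the three protein families with
established roles in thermal stress — heat shock proteins, antioxidant
enzymes (superoxide dismutase, peroxidase, thioredoxin, glutathione
redox system) and the ubiquitin–proteasome system — and (ii) unigenes
carrying imbalanced SNPs. Matching is case-insensitive substring/regex
over free-text annotation, because that is what annotation tables
actually contain; ontology-id matching is out of scope.

Genotyping by high-resolution melting (HRM) distinguishes alleles by
the melting-curve shape of a 40–100 bp amplicon, which fails when (1) a
second SNP sits within ±20 bp (closed window) of the target, (2) the
substitution is an A/T or G/C transversion (the two amplicons melt at
indistinguishable temperatures), or (3) no amplicon window of feasible
length fits on the unigene. `hrm_feasibility()` reports the *first*
failing rule in that fixed order — flanking, transversion, amplicon —
chosen so that the cheapest wet-lab objection is reported first.
Amplicon feasibility is sequence-window availability only; primer
thermodynamics are deliberately out of scope.

## Degree-hour phenotyping and extreme sampling

Under a chronic stress ramp (default: start at 26 °C, +0.5 °C per
day), heat tolerance is the accumulated excess temperature above a
baseline until death: the integral of max(T(t) − baseline, 0), with
the schedule a step function. The baseline defaults to 25 °C, the
usual acclimation temperature, but published degree·hour figures
rarely state their baseline convention — users comparing against
external numbers should check this. The last scheduled temperature
persists past the final breakpoint by default (`final_hold = TRUE`),
matching how a ramp that reaches its ceiling is actually run; a strict
mode errors instead. Mortality checks at fixed clock times are
modelled by snapping death times *up* to the next checkpoint.

`select_extremes()` ranks individuals once, ascending by
(degree-hours, id), and takes the first *k* uncensored individuals as
the heat-susceptible group and the last *k* overall as the
heat-resistant group: the lexicographic id tie-break makes selection
deterministic, censored survivors can only be resistant, and a single
shared ranking guarantees the two groups are disjoint whenever
2k ≤ n, even with heavy ties.

## QC and the allelic association test

Before testing, the genotype matrix is cleaned with strict thresholds,
in the conventional order individuals → SNP missingness → exact HWE
(overridable): individuals with ≥ 10% missing calls, then SNPs with
≥ 50% missing calls, then SNPs with exact Hardy–Weinberg p ≤ 0.001 are
removed, each with a ledger entry. HWE is computed on all genotyped
surviving individuals, cases and controls combined — computing it
within controls only is a defensible alternative, but with
extreme-sampled "controls" the combined sample is the less biased
choice and is the default here. The HWE test is the exact conditional
test (no mid-p): given the allele counts, the p-value sums the
probabilities of all heterozygote counts whose point probability does
not exceed the observed one.

The association statistic is the two-sided Fisher exact test on the
2 × 2 table of allele counts (two per genotyped individual) in the
susceptible vs resistant groups. Two-sided conventions differ between
implementations; this package uses the point-probability ordering —
the p-value sums all tables with the observed margins whose
hypergeometric point probability is ≤ the observed table's, with a
relative guard of 1e−7 absorbing floating-point ties — which is the
convention of the standard association tooling. Both exact tests are
verified against full choose()-based enumeration oracles over *all*
2 × 2 tables with N ≤ 40 and all genotype configurations with N ≤ 50,
to 1e−12.

`reconstruct_counts()` inverts published allele-frequency tables:
given a frequency printed to *d* decimals, it enumerates even allele
totals n ∈ [48, 96] and counts k whose ratio rounds (half-up) to the
printed value, returning the largest-n match — the explanation with
the least missing data — and flagging ambiguity. Half-up rounding is
implemented as |k/n − printed| ≤ 0.5·10⁻ᵈ (plus 1e−12 slack); base R's
`round()` rounds half to even and cannot be used for this.

No multiple-testing correction is applied to the association output by
default (published candidate-gene tables report raw Fisher p);
`bh_adjust()` is available when a corrected column is wanted.

## Expression and allele-specific qPCR

RPKM is reads × 10⁹ / (length × library total). Differential
expression between two libraries is called per gene from the 2 × 2
table (gene reads vs remaining reads in each library) with the same
two-sided Fisher test, BH-adjusted across genes; a gene must pass both
the FDR (< 0.01) and the two-fold RPKM-change rule. The per-gene count
statistic is pluggable (`test_fun`): the Fisher table test is this
package's choice of two-library test, and an alternative such as
Audic–Claverie can be slotted in without touching the calling rule.

The qPCR arithmetic follows the Livak 2^−ΔΔCT method, with replicate
CTs averaged before any Δ is formed (qPCR reports conventionally
present means of technical triplicates). For allele-specific
expression, the efficiency coefficient 2^−ΔCT measured on a
heterozygote's *genomic* DNA — where both alleles are necessarily
equimolar, so any CT difference is pure primer-efficiency artifact —
divides the raw cDNA allele ratio to give the true allelic expression
ratio. The whole chain is exactly invertible at zero noise, and the
test suite drives a planted ratio of 4 with coefficient 1.11 through
generator → coefficient → normalization and recovers both exactly.

## What the simulators emulate — and what they do not

All randomness is drawn from one seed per generator call (the caller's
RNG state is restored); multi-stage simulations derive stage seeds as
seed, seed + 1, … from one master seed.

* `sim_reference()`: i.i.d. uniform-base unigenes, ≥ 100 bp so
  flanking-window rules always have room.
* `sim_pooled_calls()`: plants a chosen number of SNPs per category,
  with genotypes that satisfy the category definitions exactly. Site
  depths follow a negative binomial (mean 40, dispersion 6) clipped to
  [1, 150], so both depth-filter tails occur at realistic rates;
  heterozygous allele depths are binomial around the true pool
  frequency; genotype scores are normal (60, 15) floored at 30.
  Deliberate violators of each quality rule (score, depth,
  minor-allele) are forced into that rule's rejection region and
  recorded in the truth table; they are planted as pool-specific SNPs
  of one designated pool so an asymmetric rejection can never silently
  flip a shared SNP's category. Density violators are planted as
  clusters of six SNPs within one 51-bp window; all other planted SNPs
  are kept ≥ 51 bp apart so they can never trip the density rule by
  accident.
* `sim_cohort()`: panel genotypes under Hardy–Weinberg equilibrium;
  death times exponential with the hazard multiplied by
  `odds_ratio` per risk-allele copy at the planted effect SNP —
  closed-form, and sufficient for rank-based extreme selection;
  survivors at schedule end are censored there.
* `sim_qpcr()`: CT tables whose gDNA heterozygote records encode only
  the efficiency term and whose cDNA records additionally encode the
  allele ratio and condition fold, in technical triplicate.

Real data differ in ways these generators do not model: linkage
disequilibrium among SNPs, allele-specific expression biasing pooled
RNA-seq frequencies away from population allele frequencies, mapping
and assembly artifacts beyond simple depth pathologies, and
non-exponential mortality dynamics. Passing tests therefore certify
the *computational chain* — filters, classification, statistics, and
their boundary behaviour — not robustness to those biological
complications.

## Numerical choices and known limitations

* Exact-test tie handling uses a relative guard of 1e−7, matching the
  reference implementations; enumeration-oracle agreement is asserted
  to 1e−12.
* Degree-hour integration is closed-form per schedule interval and is
  checked against midpoint quadrature on a breakpoint-aligned fine
  grid to 1e−9 over 1,000 random schedules.
* The exact Fisher test's p-values are discrete: at 48 + 48
  individuals (96 alleles per group) the null distribution has sizable
  atoms — including one at p = 1 — so null p-values are *valid*
  (P(p ≤ t) ≤ t, asserted by simulation) but visibly super-uniform,
  and a Kolmogorov–Smirnov uniformity test over a few hundred
  replicates will reject even though the test is correctly calibrated
  at its achievable levels. Uniformity holds only as the
  continuous-test idealization.
* Simulation problem sizes in the test suite (tens of unigenes,
  hundreds of SNPs, cohorts of ≤ 96, 100–200 association replicates)
  were chosen as the smallest sizes at which the checked properties
  are statistically sharp.

## A worked run

```{r pipeline, eval = FALSE}
ref <- sim_reference(60, c(300, 1500), seed = 11)
pools <- sim_pooled_calls(ref, seed = 11)
north <- filter_variants(pools$north)$kept
south <- filter_variants(pools$south)$kept

classified <- classify_snps(north, south)
category_counts(classified)

imb <- score_imbalance(classified, north, south)
candidates <- screen_hrm(classified, ref) |>
  filter(hrm_status == "pass")

cohort <- sim_cohort(96, odds_ratio = 4, maf = 0.3, seed = 12)
groups <- select_extremes(cohort$phenotypes, k = 48)
qc <- qc_genotypes(cohort$genotypes)
assoc <- run_association(qc$matrix,
                         groups$susceptible$individual_id,
                         groups$resistant$individual_id)
tidy(assoc)
autoplot(assoc)
```
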