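---
title: "Methods: paired promoter-methylome and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired promoter-methylome and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promethyl)
```

# Overview

`promethyl` implements a paired tumor/non-tumor promoter methylome
analysis for targeted bisulfite sequencing. The pipeline consumes
per-CpG methylated/unmethylated read counts restricted to promoters
(defined as -2200 bp to +500 bp around each TSS, strand-aware, 2700 bp),
per-sample gene counts from RNA-seq, and a pairing manifest. Its unit of
inference is the *patient pair*: differentially methylated regions (DMRs)
and differentially expressed genes (DEGs) are called within each
tumor/normal pair, and genes are promoted to candidates by recurrence
across pairs plus an inverse methylation-expression relationship.

A synthetic-cohort generator with planted ground truth accompanies the
pipeline so that every stage can be benchmarked end to end.

# Methylation quantification

A CpG's methylation level is the beta value `count_M / (count_M +
count_U)`; M values are the log2 odds `log2((beta + eps)/(1 - beta +
eps))` with `eps = 0.01` to keep fully (un)methylated sites finite. The
epsilon is a numerical guard, not a biological parameter; any site-level
analysis in this package operates on beta values, with M values exposed
for variance-stabilized downstream use.

Coverage files use the bismark-coverage dialect (1-based inclusive
positions); internally all coordinates are 0-based half-open. Watson and
Crick strand evidence for one CpG (records at the C and at the
following G) is merged by summing counts, since both strands measure the
same methylation state of the dinucleotide.

Depth filtering keeps sites covered at `min_depth` (default 4, ties
kept) either in every sample (`all_samples`, the common-site matrix used
for clustering and PCA) or independently per sample. Promoters without
retained sites yield missing means; rows with missing values are dropped
before clustering and PCA (complete-case), so those analyses always see
a fully observed matrix.

# Promoter annotation and CpG-content classes

CpG islands are detected with the classical criteria (windows of 200 bp,
GC fraction at least 0.5, observed/expected CpG ratio at least 0.6, step
1, overlapping qualifying windows merged), with expected CpGs computed
as `#C * #G / window_length`. Overlapping `CG` dinucleotides are counted
by a single-step scan; windows with more than 10% N are skipped.

Promoters are classified by their 500-bp windows: HCP (high CpG content)
if any window reaches CpG ratio 0.75 and GC 0.55; LCP (low) if no window
reaches ratio 0.48; ICP otherwise. The full 2700-bp promoter is scanned
at step 1; the test suite checks the classifier against an exhaustive
position-list oracle, so any step-based shortcut would be caught.

# Per-pair DMR detection

Per CpG, tumor versus normal counts within one pair form a 2x2 table
tested with a two-sided Fisher's exact test (`fisher_exact_2x2()`, a
vectorized tail-sum implementation that agrees with full hypergeometric
enumeration to 1e-12). A site is *differentially methylated* when its
BH-adjusted p-value is below 0.05 and the within-pair beta difference is
at least 5%.

Regions are called by a sliding window of 5 consecutive CpGs (step 1)
within each promoter. Two qualification rules are available:

* **`method = "pooled"` (default).** The window's counts are summed over
  its CpGs and tested exactly; window p-values are BH-adjusted across
  all windows of the pair. A window qualifies when its q-value is below
  0.05, the lower 95% Wald confidence bound of the pooled beta
  difference is at least `min_mean_delta` (default 0.1) in the window's
  direction, and at least 3 of its sites support that direction with
  |delta beta| of 5% or more, with no opposing supporting site. This is
  the region-level reading of the analysis: the window, not the site, is
  the tested unit. The confidence-bound requirement exists because the
  observed delta of the most extreme of many overlapping windows is
  selection-inflated; requiring the *lower confidence limit* to clear
  the threshold blocks that inflation. At ~23x per-CpG depth a 5-CpG
  window pools roughly 115 reads per side, giving essentially full power
  for a planted 0.4 beta shift while small biological fluctuations
  (~0.05) stay below the confident-effect bar.
* **`method = "site_count"`.** A window qualifies when at least 3 of its
  sites are individually significant (site q below 0.05, |delta| >= 5%)
  in one direction, none significant in the other, and their mean delta
  is at least 0.1. At 23x depth the per-site exact test retains only
  ~0.75 power after any FDR adjustment, which caps the per-pair recovery
  of true promoters; the rule is kept for comparison but is not the
  default.

For the site-level q-values, BH is applied within (pair, promoter) by
default (`bh_scope = "promoter"`): the promoter is the unit about which
claims are made, and a pooled correction across the ~20,000 promoter
CpGs of a pair at this depth leaves per-site power near 0.3, too little
to assemble regions from. Pair-wide pooling remains available
(`bh_scope = "pair"`).

Same-direction qualifying windows of one promoter merge into a single
DMR by default (`merge_gap_cpgs = Inf`): the 2.7-kb promoter is treated
as one regulatory unit, so each pair contributes at most one
hyper-methylated and one hypo-methylated region per promoter, matching
the observation that recurrent genes carry one or two DMRs. Setting
`merge_gap_cpgs = 0` restores the strict merge in which only windows
sharing a CpG coalesce; intermediate values allow bounded gaps.

A gene counts toward recurrence in a pair when it has one or two DMRs
there (more are treated as an unstable call and disqualify the pair);
a gene is recurrent when it counts in at least 6 of 8 pairs.

# Per-pair DEG calling

Expression is quantified as RPKM (reads per kb of gene model per million
mapped reads). Without replicates within a pair, each gene's tumor count
is tested against `Binomial(c_T + c_N, L_T / (L_T + L_N))` — the exact
conditional test of equal relative abundance in two libraries — two
sided, BH-adjusted across genes within the pair. A gene is a DEG when
the RPKM fold change (pseudocount 0.1 on both sides) exceeds 2 in either
direction and the q-value is below 0.01. Recurrence again asks for a
consistent direction in at least 6 of 8 pairs.

# Integration

A candidate gene must, in at least 5 of 8 pairs simultaneously, carry a
qualifying promoter DMR and a significant DEG (the joint reading of
"selection criteria in at least 5 pairs"; an independent-support reading
is available via `mode = "independent"`). The methylation-expression
relationship is *negative* when the directions oppose (hyper & down, or
hypo & up); `filter_negative()` keeps only those and reports the
hyper/hypo split.

# Cohort statistics

* **Clustering.** Average linkage on 1 - Pearson correlation between
  sample profiles (Euclidean switchable). Edge support is the bootstrap
  probability (BP): the fraction of feature-resampled trees containing
  the same leaf clade, from at least 100 resamples. AU (multiscale
  bootstrap) support is deliberately not computed; BP answers the same
  qualitative question and needs no multiscale machinery.
* **Top variable regions.** Per CpG island (or any region), a chi-square
  homogeneity statistic on the 2 x n_samples table of summed
  methylated/unmethylated counts; regions ranked by ascending p (ties:
  descending statistic, then identifier).
* **PCA.** SVD of the feature-centered matrix; sample scores and
  explained-variance fractions; the largest-magnitude loading of each
  component is made positive so signs are reproducible.
* **Group variance.** Per-feature within-group variances, the fraction
  of features with larger tumor variance (constants excluded) and a
  two-sided sign test on that fraction; within-group chi-square
  homogeneity statistics are attached when count matrices are supplied.
  The exact form of the original chi-square confirmation is not
  recoverable, so this declared substitute is documented as such.
* **Validation.** Per gene amplicon across 78 pairs: Student's paired
  t-test on beta, the mean within-pair difference, and counts of pairs
  in the difference categories [0, 0.05), [0.05, 0.1), [0.1, 0.2),
  [0.2, 1] (right-open bins, closed top; only the 0.2 headline cut is
  externally fixed, the finer cuts are conventional). A zero-variance
  difference vector returns an undefined-statistic flag rather than an
  error.
* **qPCR.** Relative expression by delta-delta-Ct, normalized to a
  reference gene (typically GAPDH): `ratio = 2^-((Ct_t,T - Ct_ref,T) -
  (Ct_t,N - Ct_ref,N))`, replicates averaged per condition.

# The synthetic cohort generator

`simulate_cohort()` emulates the study design: a discovery cohort of 8
tumor/normal pairs over 300 genes and a validation cohort of 78 pairs of
per-amplicon mean betas.

* **Genome.** One gene per 4-kb slot on a single chromosome; promoter
  sequences synthesized in three styles — a CpG-island-like GC-rich core
  for HCP, CpG-depleted background for LCP, an intermediate-density core
  for ICP — in proportions 0.5/0.3/0.2. Background sequence is CpG
  depleted (most CG dinucleotides mutated), mimicking the deamination
  history of real genomes; without that depletion random sequence has an
  observed/expected CpG ratio near 1 and no LCP promoters would exist.
  Each emitted promoter is re-checked with `classify_promoter()` and
  resampled (bounded retries) until it classifies as intended, so the
  ground-truth label always matches the classifier.
* **Methylation.** Class baselines 0.1 (HCP), 0.4 (ICP), 0.7 (LCP) —
  modelling choices, as no per-class baselines are externally fixed —
  with per-gene (SD 0.05) and per-site (SD 0.05) jitter shared across
  samples, and per-gene per-sample noise (SD 0.03) representing
  biological and sampling variability between the two tissues of a
  patient. Planted DMR genes (10% hyper, 5% hypo) shift tumor beta by
  +-0.4 in a random 80% of pairs (6 carriers of 8), clipped to [0, 1].
  Hyper-methylation is planted on HCP/ICP promoters and hypo-methylation
  on ICP/LCP promoters: the baselines leave no headroom for the opposite
  assignments, and methylation change concentrates by promoter class in
  real tumors. Depth per CpG is negative binomial (mean 23, size 8) —
  capture depth is overdispersed — and the methylated count is binomial
  at the site's true beta, so counts always sum to depth.
* **Expression.** Gene means are log-normal around 100 counts (sdlog
  0.5); per-patient gene effects (sdlog 0.2) are shared by both tissues
  of a pair and therefore cancel within pair; tumor means are scaled by
  the planted fold change (4, direction opposite to the methylation
  change for every planted DMR gene, plus 5% of genes with an
  uncoupled expression change); counts are negative binomial with small
  within-pair dispersion (0.001). The dispersion is small deliberately:
  biological variability lives in the shared patient effects, so the
  within-pair comparison faced by the exact binomial test is close to
  its nominal model and null p-values are approximately uniform.
* **Validation cohort.** One mean beta per planted gene and per matched
  null gene per sample; planted genes show a +-0.3 difference in a
  random 80% of pairs (responders), with amplicon noise SD 0.05.
* **Determinism.** Every output unit draws from its own RNG stream
  seeded by (master seed, stream label), so identical configurations are
  byte-identical and adding samples never reshuffles earlier ones.

What the generator does **not** emulate: read alignment and bisulfite
conversion errors, SNPs and copy-number changes, spatially varying
methylation within a promoter (planted shifts are promoter-wide),
isoform structure, and batch effects. Passing the benchmark therefore
shows the statistical machinery is correct under the stated model, not
that the pipeline is robust to artifacts absent from the model.

# Benchmark sizes and numerical choices

The packaged checks run the discovery design (8 pairs x 300 genes,
~25,000 promoter CpGs) over 20 simulation seeds for DMR recovery (plus
20 null seeds), 20 seeds for DEG recovery, and 10 seeds for the 78-pair
validation cohort; the genome is held fixed across seeds as the common
reference while truth and counts are redrawn. These sizes give stable
aggregate estimates (binomial SE under 2% on each recovery rate) while
keeping a full run in minutes on one core.

Tie and degeneracy rules collected in one place: depth ties at the
filter threshold are kept; variable-region rank ties break by descending
statistic then identifier; candidate ordering is by support then gene
id; equal hyper/hypo counts report "hyper" as dominant (they also set
`direction_consistent = FALSE`); zero-depth beta is an error upstream of
any statistics; windows with fewer retained CpGs than the window size
produce no calls.

# Limitations

* The per-site exact test conditions on margins and is conservative at
  low depth; site-level results at 4-10x should be read as screening
  calls.
* The binomial DEG test models within-pair technical sampling only; with
  strong composition shifts (many planted changes in one direction) the
  library-ratio normalizer absorbs some signal, which mildly biases
  fold-change estimates of null genes.
* BP values are plain bootstrap proportions; they are known to be
  conservative for well-supported clades compared to AU values.
* One promoter per supplied TSS row: genes with alternative TSSs are
  represented by supplying one row per TSS.
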