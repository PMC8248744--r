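---
title: "Mapping resistance loci by bulked segregant analysis in haplodiploids: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping resistance loci by bulked segregant analysis in haplodiploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapbsa)
```

## The mapping problem

`hapbsa` implements a bulked-segregant-analysis (BSA) genetic-mapping
workflow for haplodiploid experimental evolution. The design it models is a
cross of an inbred, fully homozygous mother strain to a **single haploid
male** drawn from a genetically diverse resistant strain. Because males in
arrhenotokous species develop from unfertilized eggs, the sire contributes
exactly one allele per site, and every informative marker in the segregating
populations traces back to that one paternal haplotype. Replicated sister
populations descended from the cross are propagated for many generations
with and without pesticide exposure; pooled sequencing of each population
then estimates the frequency of the resistant-parent allele along the
genome, and regions where selected populations diverge consistently from
their paired controls are quantitative trait loci (QTL) for resistance.

The package covers the full path from raw pooled allele counts to QTL
intervals and two follow-up analyses: copy-number estimation at an
amplified candidate locus (read-depth and qPCR based), and classical
mode-of-inheritance tests from dose-response bioassays. A forward simulator
generates every input with known ground truth, so the whole pipeline is
testable end to end without external data.

## Transmitted-allele inference and site filters

At sites where the sire's source strain is homozygous, the transmitted
allele is known from the parental genotypes. At the strain's heterozygous
sites it is inferred from the offspring pools: if the non-maternal allele
appears at a frequency above `min_pool_freq_for_inference` (default 0.05)
in at least one pool, that allele was transmitted; otherwise the sire
passed the maternal allele and the site carries no information about his
haplotype. The 0.05 floor guards against sequencing-error reads being
mistaken for a transmitted allele; it is a package choice, exposed in
`site_filter_params()`.

A site is dropped for a selected/control pair when the **same allele** is at
frequency `>= 0.95` in both members — such a site is non-segregating in
that pair and contributes no contrast. The comparison is inclusive
(exactly 0.95 is dropped), and either allele near fixation triggers the
rule. A site is excluded globally only when every pair drops it; otherwise
the per-pair usability is tracked so each pair keeps its maximal
informative site set.

## Windowed scans

Allele-frequency tracks use sliding windows of 75 kb advanced in 5 kb
steps; a window is retained only if it holds at least 38 usable sites, and
windows are unweighted means of site frequencies. Windows start at
position 1 of each chromosome; trailing windows that would extend past the
chromosome end are dropped rather than truncated so the width and the
site-count criterion stay comparable genome-wide. (Whether the grid should
start at position 1 or at the first marker is a free choice; position 1 is
the default and the grid is fully parameterized in `window_params()`.)

Per pair, the windowed control track is subtracted from the selected track;
the per-pair difference tracks are averaged per window over the pairs with
data there (missingness is not propagated — dropping a window in one pair
should not blind the other ten).

The RNA-based scan works on exonic biallelic positions instead: a position
enters a pair's track when read coverage is at least 20 **in both members**
(the coverage rule is stated without naming samples in the workflow this
implements; requiring both members is the conservative reading, and it is
configurable) and the control major allele frequency is below 0.95. The
per-position absolute frequency difference is averaged in 500 kb
non-overlapping windows and then across pairs.

## Permutation threshold on the circularized genome

Significance comes from a rotation null: the chromosomes are concatenated
in order into a ring (the end of the last chromosome joins the start of the
first), each pair's windowed difference profile is rotated by an
independent uniform offset, the rotated profiles are averaged, and the
maximum absolute averaged value is recorded. Rotation preserves each
profile's internal linkage structure — the spatial autocorrelation that
makes window values non-exchangeable individually — while destroying the
alignment of pairs, which is exactly the exchangeable component under the
null of no shared selection response.

Over `n_permutations` rotations (default 10^4) the threshold is the value
exceeded by exactly `floor(fdr * n_permutations)` permutation maxima, an
empirical upper quantile of the max-deviation distribution at level 0.05 by
default. Because it is a genome-wide maximum statistic, this construction
controls a family-wise error rate; the "FDR" label is the convention of
the workflow this package follows, and outputs keep that label while this
vignette records the distinction. Windows missing in every pair are removed
from the ring before rotation (their positions are remembered for
inversion) — rotating imputed values would manufacture data; the cost is a
slight change of ring geometry relative to the physical genome.

Windows whose absolute mean difference reaches the threshold are
significant; maximal runs of contiguous significant windows become one QTL
each, runs never span chromosome boundaries, and the peak is the window of
largest absolute value (leftmost on ties, for determinism). Runs separated
by even a single non-significant window stay distinct calls. Sub-threshold
local maxima can be reported as "subsidiary peaks" (top-k by value, k = 2
by default) without any significance claim.

QTL intervals extend outward from the peak by a similarity rule: a window
is peak-similar when its value lies within 0.005 of the peak value, and the
walk continues while the most recent block of five consecutive windows
contains at least one peak-similar window; the interval spans the outermost
peak-similar windows reached in each direction.

## Copy number and dosage

Per-gene coverage matrices are normalized by median-of-ratios size factors
(per-gene geometric-mean reference over samples, genes with any zero count
excluded, per-sample factor = median ratio). Note one algebraic subtlety:
with a geometric-mean reference, multiplying one sample's counts by *c*
multiplies its factor by *c* only relative to the other samples — the
reference itself absorbs *c*^(1/m). Relative coverage divides each gene's
normalized value by its mean over a baseline group, by default the control
(single-copy) populations. Maximal runs of consecutive genes at relative
coverage `>= 1.5` become gain segments, with copies estimated as the
rounded mean over member genes (floored at 1; the raw mean is kept
alongside). The 1.5 cut separates one-copy from two-or-more-copy genes at
moderate noise. Calling is deliberately gene-level, not per-base
segmentation: the phenomenon modeled is a multi-gene amplified block, and
gene resolution keeps the detection rule transparent and exactly testable.

qPCR copy number uses efficiency-corrected relative quantification against
a single-copy reference amplicon and a calibrator sample:

CN_s = E_t^(Ct_t,cal − Ct_t,s) / E_r^(Ct_r,cal − Ct_r,s),

with replicate Ct values averaged before exponentiation and the
calibrator's copy number defined as 1. With noiseless Cts this inverts the
simulator's Ct model exactly for any efficiency in (1, 2].

Expression fold change is the ratio of group means of normalized counts.
For genes whose expression is driven purely by dosage, the DNA coverage
ratio and the RNA fold change estimate the same quantity; the package's
tests assert their agreement at the locus level (mean over the amplified
block's member genes) within 15%. With a single RNA replicate per
population and desk-scale depth, per-gene estimates carry enough
negative-binomial sampling noise that gene-by-gene agreement at 15% would
be an overclaim; locus level is also the resolution at which copies are
reported.

## Mode of inheritance

Dose-response data are fit by maximum-likelihood binomial regression with a
probit link on log10 concentration; LC50 = 10^(−α/β) with a delta-method
95% CI. Abbott's correction for control mortality is available but off by
default. Stone's degree of dominance uses base-10 logs:
D = (2·logLC50_F1 − logLC50_R − logLC50_S)/(logLC50_R − logLC50_S),
so D = 1 is fully dominant resistance and D = −1 fully recessive. The
monogenic-recessive expectation for backcross progeny is
c = 0.5·W(F1) + 0.5·W(R) per dose, tested by a chi-square goodness-of-fit
over the dead/alive cells of every dose. The degrees of freedom are set to
the number of doses: no parameter is estimated from the backcross data, so
no df is spent; doses with degenerate expectation (c of 0 or 1) are
excluded with a warning. A maternal effect is flagged when the reciprocal
F1 LC50 confidence intervals are disjoint.

## The synthetic experiment

`sim_config()` fixes the study conditions; `simulate_experiment()` emits
every pipeline input with ground truth. Defaults:

* **Genome**: three chromosomes of 7.5, 5.0 and 2.5 Mb (ordered by
  decreasing length), 2 informative-site candidates per kb. A desk-scale
  genome that still spans many windows per linkage block.
* **Cross**: mother homozygous reference everywhere; the resistant strain
  heterozygous at 60% of polymorphic sites and homozygous-alternate at the
  rest; the sire one random strain gamete. About 70% of sites end up
  informative, matching the intuition that half the strain's heterozygous
  sites are lost through the single male.
* **Design**: 11 pairs, 650 females per population, 35 generations, DNA
  pooled from up to 1,000 females (the census if smaller), pooled depth 100.
* **Life cycle**: daughters unite a recombinant maternal gamete with the
  full haplotype of a random male (sperm are clonal in haplodiploids);
  sons are unfertilized recombinant maternal gametes. Recombination is
  exactly one crossover per chromosome per female meiosis at a uniform
  position — no genetic map is assumed, and one obligate crossover gives
  realistic linkage blocks at this scale. Generation 0 is the F1: all
  females uniformly heterozygous at informative sites, males drawn from
  their gametes, which collapses the initial expansion phase into the
  neutral burn-in (only the allele frequencies at pair setup matter
  downstream, and they are exactly 1/2).
* **Selection**: viability selection each generation in the selected
  treatment, multiplicative across loci; females with 0/1/2 resistant
  alleles have fitness 1−s, 1−s(1−h), 1 and haploid males 1−s or 1.
  Defaults: three loci (two on chromosome 1, one on chromosome 2) with
  s = 0.15, h = 0.1. The dominance reflects incompletely recessive
  resistance; the selection coefficient was chosen once so that the sweep
  completes near generation 30–35 — the regime the design emulates, where
  exposure is gradual and near-fixation is reached by the end of the
  experiment. Much stronger selection fixes the resistant haplotype within
  a few generations and, because haploid males transmit whole genomes
  clonally, drags entire chromosomes along before recombination can
  decouple them, which destroys localization; dose escalation itself is
  deliberately not modeled (endpoint frequencies, not trajectories, feed
  the pipeline).
* **Sequencing**: per-site depth Poisson; alternate reads binomial at the
  pooled frequency; per-gene DNA coverage Poisson with mean scaled by the
  population's local copy ratio; RNA counts negative binomial (dispersion
  0.05) with mean scaled by copy ratio and by cis-eQTL multipliers raised
  to the local haplotype dose; one RNA replicate per population, as in the
  emulated design. RNA-scan site depth defaults to 40.
* **CNV**: a block spanning exactly five consecutive genes (~14 kb on the
  tiled gene grid) around the chromosome-2 locus, three copies per
  resistant haplotype. A population's copy ratio is the mean of
  (dose·copies + (2−dose))/2 over pooled females, so fixed resistant
  populations show a 3:1 contrast against single-copy baselines. In the
  **control** treatment the amplified haplotype pays a viability cost of
  0.1 per copy (`cnv_cost`): without exposure the amplification is purged,
  control populations converge to a single copy over the experiment, and
  the control-side allele frequency dips toward zero at this locus — the
  pattern that motivates using control populations as the single-copy
  baseline for relative coverage. Under selection the resistance benefit
  dominates and no cost is applied. With `cnv_cost = 0` (or one copy) the
  locus is fully neutral, which is how the drift-only calibration runs are
  configured.
* **qPCR**: Ct = Ct0 − log_E(copies) + Normal(0, sd), duplicates per
  sample/amplicon, target efficiency 1.9, reference 1.95, sd 0.15 cycles.
* **Dose-response**: probit classes S, F1, R with log10-LC50 0.7, 1.2 and
  3.2 (D = −0.6, incompletely recessive) and slopes ~2; backcrosses are
   50:50 F1-like/R-like mixtures under one recessive locus.

All randomness flows from the single `seed` through named substreams
(`substream_seed()`), so a fixed configuration reproduces every emitted
table byte-for-byte.

### What the simulator does not emulate

Sequence-level reads (mapping error, indels, base quality), multi-allelic
sites, dose-escalation schedules, sex-ratio dynamics, trans-regulatory
variation, and real linkage maps are all absent. Passing tests therefore
demonstrate that the pipeline's inference machinery is correct under its
own generative assumptions — not that those assumptions capture every
property of real pool-seq data. The control populations' ~0.5 baseline
frequency is a modeling consequence of the F1 founding, not an empirical
value.

## Numerical choices and degenerate inputs

* Window coordinates are 1-based inclusive internally and BED 0-based
  half-open on export; site coordinates follow VCF (1-based).
* The permutation threshold with all-zero rings is 0; a constant ring is
  rotation-invariant, so its threshold equals the constant.
* Probit fits refuse complete separation ("no partial kill") instead of
  returning a divergent slope; the monogenic chi-square refuses doses
  missing from a parent table.
* A heterozygous mother genotype marks the site `low_quality`; it is never
  silently used.
* Multi-allelic and indel VCF records are skipped with a warning; the
  analysis is SNP-based.
* Population extinction under selection raises an error naming the
  generation rather than returning an empty population.

## Problem sizes used by the test-suite and acceptance runs

The packaged checks run the default 15 Mb / 11-pair experiment with 1,000
rotations for QTL recovery, and 200 drift-only experiments on a reduced
2 Mb genome (11 pairs, depth 60, 500 rotations each) for null calibration;
unit tests use ~1.6 Mb toy genomes with 2–3 pairs. These sizes were chosen
so the full suite exercises every stage at meaningful resolution while a
complete run stays within a coffee break on a single core.
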