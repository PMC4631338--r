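---
title: "Methods: strain-specific variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-specific variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An inbred disease-model strain (here the diabetic GK rat) and its
phenotypically normal source strain (Wistar) differ at a few million
genomic sites, almost all of which are irrelevant drift fixed during
inbreeding. This package implements the comparative-genomics pipeline
that narrows those millions of differences down to a handful of
candidate genes: hard filtering of called variants, case-specific
variant derivation, consistency filtering against a multi-strain panel,
and corroboration with protein-interaction and expression evidence.
Every stage operates on genotype-level inputs (VCF, TSV matrices, BED),
never on reads: read mapping, variant calling, and annotation are
upstream tools whose outputs this package consumes.

## Variant model and genotype groups

Genotypes are diploid allele-index pairs (`0` reference, `1`/`2`
alternates), unordered, with `./.` for missing. A site is
*case-specific* when the (case, control) genotype pair falls into one of
five groups:

| group | case | control |
|-------|------|---------|
| 1 | 0/1 | 0/0 |
| 2 | 1/1 | 0/0 |
| 3 | 1/1 | 0/1 |
| 4 | 1/2 | 0/0 |
| 5 | 1/2 | 0/1 |

Anything else — including any pair with a missing genotype — is not
specific. A control genotype of `./.` is treated as non-specific rather
than specific: specificity cannot be established without observing the
control. Multi-allelic records are kept whole, because groups 4 and 5
require both alternate alleles at one site.

## Hard filters

SNVs pass when per-sample total depth ≥ 10, called allele number = 4,
base quality ≥ 30, quality-by-depth ≥ 5, and at most 4 zero-mapping-
quality reads, and when they avoid two positional artifacts: the
reference footprint of any raw indel ± 1 base, and SNV clusters (any
10-bp window holding ≥ 3 calls; all members removed). Indels pass at
depth ≥ 8 and allele number = 4. Two stated thresholds required
interpretation, which we fixed as follows and flag here for users:
"depth for each allele in per sample" is read as per-sample total depth
(a per-allele minimum of 10 would contradict the lower site minimum
used for indels), and allele number 4 is read in its VCF sense — all
four alleles of two diploid samples called, i.e. no missing genotypes.
Cluster removal drops *all* members of a violating window, not just the
excess. The rules are conjunctive, so the passed set is independent of
rule order; the filter report attributes each removal to the first
failing rule in a fixed order, and a record with a missing QC field
fails (`missing_qc`) rather than passing silently.

Differential CNV regions pass when the case/control mapped-read ratio
exceeds 2-fold in either direction (> 2 or < 1/2) and the
Bonferroni-adjusted p-value is below 0.01.

## QC statistics

Ti/Tv counts transitions (A↔G, C↔T) and transversions over the
alternate alleles carried by the case genotype, per allele at
multi-allelic sites. Homozygosity is the share of homozygous-variant
genotypes (a/a, a ≥ 1) among the strain's variant sites — that
denominator (rather than all high-quality sites) is the one that
reproduces the published reference percentages. Percentages are
reported to two decimals, rounded half away from zero; comparisons with
published values use a 0.01 tolerance because reference tables mix
truncation and rounding. Truth-panel validation reports sensitivity
(known-polymorphic positions with a call) and specificity
(known-non-polymorphic positions without one); empty truth sets yield
missing values, never 0/0.

## Density profiling

Each chromosome is tiled with fixed 1-Mb bins anchored at coordinate 0
(the grid origin is a convention we fixed; the last partial bin keeps
its true width). Density is the variant count divided by the bin's
bases covered by ≥ 3 reads; a zero-coverage bin keeps a missing density
but is retained. The SNV–indel density correlation is Pearson's r over
bins where both densities are defined, computed on per-bin densities
(not on binned frequency histograms — the other reading of the source
description; noted for users). Extreme segments are the top/bottom
`ceiling(0.05 n)` bins with coordinate-order tie-breaks; bottom bins
overlapping assembly gaps are removed first, since gap-driven low
density is artifact.

## Panel filter and OR exclusion

A protein-affecting variant (nonsynonymous, stopgain, stoploss,
splicing, frameshift indel, or exonic ncRNA) survives the panel filter
only if homozygous-variant in the focal case strain, homozygous-variant
for the *same* alternate allele in every case-consistent panel strain,
and not homozygous-variant for it in any control-background strain.
Missingness is asymmetric by design: a missing genotype in a
case-consistent strain fails the rule (homozygosity must be observed),
while a missing background genotype does not rescue exclusion (absence
of evidence cannot demonstrate the background carries the allele).
Heterozygous focal PAVs are set aside in a side list, never candidates.
Strain-group membership is configuration, not code — e.g. a type 1
diabetes model strain belongs in neither group. Olfactory-receptor
genes, a huge and rapidly mutating family, are excluded as background
mutation; genes without a model are kept with a warning.

## Phylogeny

Strain distances are Nei's dA net nucleotide substitutions,
`dA = πXY − (πX + πY)/2`, with cross- and within-strain mismatch
probabilities computed per site from the diploid genotypes (within-
strain heterozygosity is 1/2 for a heterozygote under drawing with
replacement) and averaged over the sites genotyped in both strains
(pairwise deletion — complete-site deletion would discard most of an
unevenly covered panel; the choice is recorded in output metadata).
The measure is floored at zero. Trees are UPGMA (average linkage —
`hclust(method = "average")` is exactly the unweighted pair-group
arithmetic-mean algorithm) with node heights at half the merge
distance, hence ultrametric; labels are sorted before clustering so
ties break deterministically by smallest member label.

## Enrichment

PPI edges with confidence strictly above 0.4 are kept (an edge at
exactly 0.4 is excluded). For each candidate gene, a one-sided Fisher
exact test asks whether its partner set is enriched for prior
(known-disease) genes, on the 2×2 table over a universe that excludes
the tested gene. The universe defaults to all genes incident to a
retained edge plus the prior genes — genes invisible to the PPI data
are not counted as non-partners; the whole-genome universe is available
as an option. p-values are Benjamini–Hochberg adjusted by default
(the adjustment method the source analysis used is not recorded; BH is
the community norm for enrichment screens and the method is stored in
the output), with Bonferroni as an option. The shared-partner network
weights each candidate pair by the size of their common partner set.

## Expression evidence

Differential expression per (tissue, time point) cell is a Welch
two-sample t-test with a direction-symmetric fold change on linear
intensities (`2^Δmean` when the matrix is log2; a config flag, since
public array matrices ship both conventions); a gene is DE at p ≤ 0.01
and fold change > 2. Differential co-expression uses a statistic we
call `dcz`: for each gene, the mean over the other genes of the set of
the absolute difference in Fisher-transformed Pearson correlations
between case and control samples, with significance from permutation of
condition labels (1000 by default, seeded) and Bonferroni correction
over the tested genes at 0.05. The co-expression method of the source
analysis is an unspecified internal of a published tool; `dcz` is this
package's own explicit, testable stand-in for the same concept (a
change in correlation structure between conditions) and is named in
the output metadata. Calls are combined with union semantics: DE/DC in
a tissue iff flagged at ≥ 1 time point, differential overall iff in
≥ 1 tissue.

## Evidence tiers

Candidates carry three flags: prior-gene membership, PPI enrichment
(adjusted p ≤ 0.05), and expression support. A gene is
*high-confidence* when it is a prior gene or PPI-enriched; expression
evidence is corroboration only and never promotes a gene by itself —
in the reference analysis the final high-confidence set is exactly
prior genes plus enrichment-significant genes, with expression listed
as additional evidence. Records sort deterministically by (tier,
adjusted p, gene).

## The synthetic cohort

The generator emulates every input with known ground truth: a
two-sample VCF whose genotype pairs follow the five-group mixture
(defaults 3.6% / 92.9% / 3.5% / ~0 / ~0, matching the published SNV
table), substitutions drawn to a Ti/Tv target of 2.10, per-record QC
fields with a 2% violation rate per rule; a 14-strain panel combining
tree-evolved sites (Bernoulli flips with probability equal to branch
length) with consistency-driven genotypes at the focal sites (case
strains share a case hom-var genotype with probability 0.9, background
strains leak it at 0.05, 3% of panel genotypes missing); gene models
with 15% flagged olfactory-receptor; a PPI graph in which planted genes
draw partners with prior genes upweighted 10-fold; and a log-normal
expression design over 2 strains × 3 tissues × 5 time points × 5
replicates with planted 4-fold DE genes and planted correlation flips
(+0.9 case / −0.9 control). Two 10-Mb chromosomes keep 1-Mb binning
meaningful (20 bins) at desk scale. One global seed drives independent
per-component substreams, so regenerating one component leaves the
others byte-identical. Enrichment and expression signals are planted at
genes the ground truth says survive the panel filter, so end-to-end
recovery is a measurable property rather than a coincidence.

What the generator does *not* emulate — and hence what green tests do
not show about real data: regional mutation-rate variation (synthetic
SNV and indel densities are uncorrelated, unlike the strong
co-localization seen in real genomes), linkage structure, allele-
frequency spectra, annotation errors, batch effects in expression, and
cross-dataset allele-representation mismatches between a call set and a
panel. The synthetic prior-gene fraction (100 of 400 genes) is far
higher than a real genome's so that hypergeometric margins stay
non-degenerate at desk scale.

## Calibration and numerical choices

Type-I calibration is checked on null simulations. The t-test rejection
rate at α = 0.01 and the permutation-based DC rejection rate at
α = 0.05 sit within 3σ binomial bands of nominal. The one-sided Fisher
exact test, however, is discrete and conservative: its exact size at
α = 0.05 for realistic partner-set margins is 0.015–0.047, computable
in closed form from each test's hypergeometric margins. Its null
calibration is therefore checked against that exact discrete-null
expectation (with a guard that the rate never exceeds nominal plus
binomial noise) — testing a discrete exact test against a continuous
nominal band would mistake a theorem for a bug. Permutation p-values
use the add-one estimator `(1 + #{perm ≥ obs})/(1 + B)`, so they are
never zero and are reproducible under a fixed seed. Degenerate inputs
follow stated rules: zero-variance expression with equal means gives
p = 1, with unequal means p = 0 (fold change decides); constant genes
are skipped from co-expression with a warning; empty panels pass
variants through with a warning; an empty truth set yields a missing
percentage.

Problem sizes used by the test-suite and acceptance runs — 10⁵ variants
for mixture/Ti-Tv convergence, 2 500 panel sites for tree recovery, 25
simulated cohorts for enrichment recovery, 100–200 for null
calibration, 200–400 permutations per DC test — were chosen as the
smallest sizes at which the checked properties have comfortable
statistical margins.

## Known limitations

The panel filter assumes the panel and the call set index alternate
alleles consistently; with real multi-source data a normalization step
would be needed first. The DC statistic is a stand-in (see above), and
its power at the realistic 5 replicates per cell is low — the planted
correlation flips are demonstrated at 20 replicates, matching the
sample size at which such effects are detectable at all. Genome-scale
published counts (millions of specific SNVs, the observed density
correlation, the specific named genes) require the original sequencing
and expression data and are out of scope; the machinery that would
compute them is what the property suite covers.
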