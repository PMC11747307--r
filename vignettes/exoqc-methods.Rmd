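---
title: "Quality control and validation of family-based exome cohorts with exoqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control and validation of family-based exome cohorts with exoqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoqc)
```

## The problem

Multi-sample exome callsets produced by joint variant calling contain three
kinds of error that downstream rare-variant analyses cannot tolerate:
samples that are not what they claim to be (swaps, duplicates, contaminated
or degraded libraries), variant records that are artefacts of library
preparation or mapping rather than biology, and individual genotype calls
too weakly supported to use. `exoqc` implements the post-calling stages
that separate these from the signal in family-based birth-cohort data:
per-sample metric screening, ancestry assignment, identity and relatedness
resolution, random-forest variant scoring combined with genotype-level
filters, and a set of validation analyses (ultra-rare burden scores,
DNA-source comparisons, genetic prevalence) that probe whether the filtered
data behave the way population genetics says they should.

Because real birth-cohort genotypes are access-restricted, the package
carries a first-class synthetic cohort generator. Every property the
pipeline is supposed to detect is injected with truth labels, so the whole
chain is testable end to end on a laptop.

## Sample-level QC

Before per-sample metrics are computed, genotypes with `DP < 20`,
`GQ < 20`, or heterozygous allele balance `< 0.25` are masked
(`prefilter_genotypes()`). The masking is deliberately separate from the
formal genotype QC later: its only job is to stop metrics from being skewed
by calls that no reasonable filter would keep. All threshold comparisons in
the package follow one convention: a value *strictly below* the threshold
fails, so `DP = 20` passes.

`compute_sample_metrics()` counts non-reference genotypes per sample (SNVs,
transitions, transversions, insertions, deletions) and forms the Ti/Tv,
ins/del and het/hom ratios plus the heterozygosity rate. Ratios with a zero
denominator are reported as `NA` with a flag, never as `Inf`, and are
excluded from outlier bounds. `flag_outliers()` screens each metric within
each cohort-by-population stratum against `median ± 4·MAD`. The MAD is the
raw median absolute deviation with **no** 1.4826 Gaussian consistency
factor: the bound is defined directly in MAD units, and the factor is
exposed as `mad_constant` for anyone who wants the Gaussian-calibrated
version. When a stratum's MAD is zero the bounds collapse to the shared
median and equal-valued strata flag nothing; strata below `min_stratum`
samples are skipped with a warning rather than silently screened.

Contamination is consumed, not estimated: free-mix scores arrive as sample
metadata and `screen_contamination()` applies a strict `> 0.05` rule under
a `remove` or `flag` policy — both appear in practice, with removal the
conservative choice when a cohort also carries library artefacts.

Genetic sex (`infer_sex()`) uses the X-chromosome inbreeding coefficient
`F = (O_hom − E_hom)/(n − E_hom)` on common, well-called X variants
(internal AF ≥ 0.01, call rate ≥ 0.99; the expectation uses
stratum-specific allele frequencies when strata are given) together with
normalized Y coverage. Assignment uses fixed cuts — `F > 0.8` and Y depth
`> 0.3` for XY, `F < 0.2` and Y depth `< 0.1` for XX — rather than a fitted
mixture: the two clusters are visually obvious in real data and fixed cuts
are reproducible. Anything between the cuts stays `undetermined` and is
kept with a flag, never guessed.

## Ancestry assignment

PCA variants are autosomal biallelic SNVs intersected with the reference
panel, with call rate ≥ 0.99, minor allele frequency ≥ 0.05, exact-test
Hardy–Weinberg p ≥ 1e-5, outside long-range LD regions, and
non-palindromic (ref/alt not A/T or C/G). The HWE filter uses the exact
conditional test (mid-p available but off); a bundled GRCh38 region list
provides the long-range LD default and is replaceable by any BED file.
`ld_prune()` is greedy windowed pruning at r² ≤ 0.2, dropping the later
variant of an offending pair, which guarantees no kept pair within a window
exceeds the bound.

Cohort and panel genotypes are merged (not projected), mean-imputed,
standardized and decomposed with PCA; a probabilistic classifier trained on
the panel labels over the leading 10 components (configurable — the number
is a default, not an externally validated constant) predicts each cohort
sample. The classifier is a bagged ensemble of extremely randomized trees:
all components are available at every split (`mtry` = all), leaves are
grown pure, and split points are drawn at random. The randomized split
points matter — with deterministic splits every tree cuts the gap between
two well-separated clusters at nearly the same place, so even a sample
exactly midway is assigned with spuriously high confidence. Random splits
spread the decision boundary across the gap: cluster members keep
probabilities near 1 while intermediate (admixed) samples draw mixed votes
and fall through to `"oth"` at the 0.9 probability cutoff.

## Identity and relatedness

`genotype_discordance()` is the fraction of discordant genotype classes at
sites non-missing in both members of a pair; a pair matches when the score
is `< 0.05`, and fewer than 200 shared sites yields `unevaluable` (kept
with a flag — a conservative non-verdict, not a pass). Kinship
(`estimate_relatedness()`) is the robust within-pair estimator
`φ = (N_het,het − 2·N_IBS0) / (N_het,i + N_het,j)` over autosomal common
SNVs, which needs no cohort allele frequencies and is therefore insensitive
to population structure. Degrees follow the standard windows (duplicate/MZ
φ > 0.354; first-degree (0.177, 0.354], split into parent-offspring versus
full siblings at IBS0 < 0.005; second-degree (0.0884, 0.177]). The X
chromosome is excluded: a father–son pair is legitimately opposite-
homozygous on X, which would corrupt IBS0.

Array mismatches resolve through four scenarios: remove when no sequenced
first-degree relative can vouch for the sample, remove when relatives are
present but genetically wrong, keep when relatives confirm (the mix-up is
then in the array data), keep when the best hit is the expected sample's
monozygotic twin. Family-consistency removals implement the two-branch
rule: a discordant parent-child pair loses both members when nothing else
in the family confirms them, and only the parent when the other parent
checks out. Duplicate groups keep declared twins, resolve intentional
re-sequencing by a best-2-of-3 comparison on bait coverage, depth at called
sites and genotyping rate (an all-tie breaks on the lexicographically
smaller id, logged), and are removed wholesale when identifiers are
discordant and nothing validates them. All decision functions are pure:
the same inputs always produce the same decisions.

## Variant and genotype QC

Training labels: a site failing any hard filter (`QD < 2`, `FS > 60`,
`MQ < 30`) is a negative; a truth-set member that passes the hard filters
is truth; everything else is unlabelled. A truth-set member that fails a
hard filter is labelled negative — the hard filters define "erroneously
called" and external membership does not override that.

Features follow the standard site-level set (QD, SOR, MQ, rank sums,
allele-structure flags) plus mean heterozygous allele balance and an
`is_ca` indicator for C>A/G>T SNVs, the fingerprint of the OxoG
(8-oxo-guanine) library artefact. The indicator can be switched off for
cohorts sequenced after a library-prep fix. Missing numeric features are
median-imputed with a missingness indicator, since absence (e.g. rank sums
at sites without het carriers) is itself informative. One probability
forest (500 trees, inverse-frequency class weights, fixed seed) is trained
on the labelled sites of a single training contig — chr20 by default,
configurable — and scores every variant; SNVs and indels share the model,
with the type features letting trees specialise.

Scores are ranked into 100 near-equal-occupancy bins (bin 1 best). Equal
occupancy was chosen over equal score width because forest scores pile up
near 0 and 1, where equal-width bins would be mostly empty; ties break on
the variant key so binning is deterministic. `cumulative_tp_fp()` gives the
cumulative truth/negative retention curves over bins; `apply_profile()`
implements the integrated filter: mask genotypes below the profile's
DP/GQ/het-AB thresholds, then drop variants whose forest bin exceeds the
cutoff or whose post-masking genotyping rate (over all samples, before any
variant drop) is below the minimum. Profiles hold separate SNV and indel
settings and nest naturally into relaxed/medium/stringent tiers; the
released annotation (`write_release_vcf()`) never removes anything — it
writes per-variant passing percentages into INFO and per-genotype 0/1 flags
per profile into FORMAT.

Two calibration metrics close the loop. The transmitted/untransmitted
ratio (`tu_ratio()`) looks at synonymous alleles seen in exactly one
parent: under unbiased calling these reach the child half the time, so the
ratio sits near 1 and a filter that preferentially eats child het calls
drags it down. The singleton count is taken **among parents**: counting
the whole dataset would disqualify every transmitted allele (parent plus
child makes two copies), collapsing the metric to zero by construction, so
the whole-dataset variant exists only as an explicitly degenerate flag.
`truth_sample_eval()` scores precision and recall of a benchmark sample's
retained calls against its authoritative variant list by exact
contig/pos/ref/alt match, zygosity ignored by default (a flag restores
strict zygosity). `evaluate_grid()` assembles the five selection metrics
for every candidate profile; choosing the profile is a human decision on
that table, not an optimisation the package performs.

## Validation analyses

Rarity: rare means internal AF < 0.1% and external reference AF < 0.1%
(plus a per-population maximum AF < 0.1% in multi-ancestry cohorts);
ultra-rare additionally requires external AF < 0.003%. Variants absent
from the reference count as frequency zero with a provenance flag.
High-confidence PTVs are splice-donor, splice-acceptor or frameshift
variants, or stop-gained with CADD > 25, all requiring the LOFTEE-style
high-confidence flag (missing flag → not a PTV, conservatively).

The burden score aggregates selection coefficients over the distinct genes
carrying a qualifying variant:

$$S_{het}\,burden_i = 1 - \prod_{g}(1 - s_{het,g})$$

so multiple hits in one gene count once and the score is strictly
increasing in any gene's constraint. Associations use `glm()` with sex and
three principal components as covariates; quantitative phenotypes are
Blom-rank-normalised (`z = Φ⁻¹((r − 3/8)/(n + 1/4))`, average ranks for
ties) and logistic separation is flagged rather than silently reported.
The synonymous-variant burden serves as the negative control throughout.

DNA-source checks: per-gene carrier counts compare blood- versus
cell-line-derived samples by two-sided Fisher's exact test with a
Bonferroni family of 18 tests (2 consequence classes × 3 stringencies ×
3 missingness filters) per gene, and a linear regression of per-sample
counts on DNA source plus three PCs estimates the mean somatic excess of
cell-line samples.

Genetic prevalence compares the count of maximally unrelated children
homozygous for a flagged pathogenic allele (compound heterozygotes are
deliberately out of scope) with the count expected from population
incidence. The expected count is `round(N × incidence)` and the two-sided
exact Poisson test sums the probabilities of all outcomes no likelier than
the observed one. The test mean defaults to the **rounded** expectation:
anchoring both the test and the exact (Garwood) confidence interval
`[χ²(0.025, 2c)/2, χ²(0.975, 2c+2)/2]` on the same integer keeps the
reported triple (expected count, CI, p) internally consistent; the
unrounded mean is available via `round_mean = FALSE` and typically moves p
by a couple of percent. "Maximally unrelated" is a greedy
maximum-independent-set: repeatedly drop the sample with the most kinship
links above 0.0884 until none remain — simple, deterministic and within
one sample of optimal on pedigree-structured data.

## The synthetic cohort generator

`simulate_cohort()` draws ancestral allele frequencies from a Beta(0.6, 6)
spectrum (rare-shifted, exome-like), diversifies populations by a
Balding–Nichols model at Fst 0.1 — enough for cleanly separable PCA
clusters at a few hundred common SNVs — and transmits parental alleles to
children fairly. Depth is Poisson with mean 60 (the cohorts it emulates
average 62–74×), GQ is drawn conditional on DP, allelic depths are binomial
around 0.5 for hets, and 0.2% of genotypes are missing. X-chromosome sites
are simulated with hemizygous males coded homozygous; Y coverage is a
per-sample metadata column because the sex check consumes only its total.
Genotype likelihoods are not simulated — nothing downstream reads them.
Exactly one alternate allele per record, with multiallelic history carried
only by the `was_split`/`n_alt_alleles` annotations, matching a
split-multiallelic release. All coordinates are 1-based.

`inject_error_modes()` layers the failure modes with truth labels:
artefact sites are 100% C>A/G>T by construction, confined to a fraction of
batches, with depressed QD (0.5–6, so a share also fails the hard filters,
as in real data) and het allele balance near 0.22; the per-sample artefact
burden is a free parameter since its real-world magnitude is only loosely
characterised ("roughly three-fold" SNV excess in the worst-affected
samples). Contamination mixes a donor's genome at weight `w`: hom-ref
sites where the donor carries the alternate become hets with allele
fraction `w·d/2` (d = donor dosage), and hom-alt calls with contaminant
ref reads demote to apparent hets — the classic het-excess/hom-deficit
signature that the MAD screen catches. Swaps exchange genotype columns but
not metadata; duplicates append a re-sequenced copy with fresh coverage
metrics; cell-line parents gain private variants in random genes.

Error-mode rates default to zero: the base configuration is the clean
cohort, and every scenario (and test) states exactly which modes it turns
on.

What the generator does **not** emulate — and what green tests therefore do
not show about real data: linkage disequilibrium beyond what pruning tests
need (sites are independent given the allele frequency), indel-specific
error processes, batch effects other than the OxoG artefact, genotype
likelihood miscalibration, and the long tail of real-world metadata
problems. Results on synthetic cohorts demonstrate that the machinery is
correct, not that any particular real callset is clean.

## Problem sizes and numerical choices

The test suite runs cohorts of roughly 150–340 samples at 2,500–6,600
sites, a scale chosen so the complete suite executes in about a minute
while keeping at least ~2,000 common SNVs available to the kinship
estimator (where its degree classification is exact on simulated
pedigrees). The trio-calibration analysis uses 2,000 trios × 10,000
singleton sites, giving a binomial standard error of 0.5% on the
transmitted fraction. Forest training uses 500 trees and a fixed seed;
rank tie-breaks (score binning, duplicate resolution) are lexicographic
and deterministic. Exact tests are validated against brute-force
enumeration (hypergeometric for Fisher, outcome summation for Poisson, an
all-pairs r² scan for pruning) in the test suite.

## Known limitations

* Contig naming assumes the `chr1`…`chr22`, `chrX` convention of the
  GRCh38-style inputs the pipeline targets.
* The greedy unrelated-selection and LD-pruning procedures are
  order-deterministic heuristics, not global optima.
* `read_callset()` loads the full genotype matrix into memory; chromosome-
  sized shards of biobank-scale callsets are the intended unit of work.
* De novo mutation QC and copy-number calling are out of scope, as is any
  re-estimation of contamination from reads.
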