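# exoqc — post-calling QC and validation for family-based exome cohorts

`exoqc` implements the quality-control stages that sit between joint
variant calling and analysis for multi-sample, family-based exome
sequencing cohorts, together with the validation analyses used to judge
whether the filtered data behave like clean population-genetic data. It is
aimed at analysts curating birth-cohort or biobank-style callsets who need
sample-, variant- and genotype-level QC that is reproducible and testable
without access to restricted genotypes.

The pipeline covers:

* **Sample QC** — lane-metric screening (Q30 < 75 rejects), genotype
  pre-filtering (DP/GQ < 20, het allele balance < 0.25), per-sample metrics
  (Ti/Tv, ins/del, het/hom, heterozygosity), population-stratified outlier
  removal at `median ± 4·MAD` (raw MAD, no consistency factor),
  contamination policy on free-mix scores, and sex inference from the
  X-chromosome inbreeding coefficient plus Y coverage.
* **Ancestry** — variant filtering (call rate, MAF, exact HWE, long-range
  LD regions, palindromes), greedy LD pruning at r² ≤ 0.2, merged PCA with
  a labelled reference panel, and per-sample continental assignment by a
  probabilistic tree ensemble over the leading components, with an `oth`
  label below probability 0.9.
* **Identity** — exome-vs-array discordance (match < 0.05), robust
  within-pair kinship `φ = (N_het,het − 2·N_IBS0)/(N_het,i + N_het,j)`
  with standard degree windows, the four array-mismatch decision
  scenarios, the two-branch family-consistency rule, 2-of-3 duplicate
  resolution, and sex-consistency removal.
* **Variant & genotype QC** — truth/negative labelling (negatives fail
  `QD < 2`, `FS > 60` or `MQ < 30`), a 500-tree random forest trained on
  one contig and applied to all variants, percentile binning, cumulative
  truth/negative curves, and an integrated grid of forest-bin ×
  DP × GQ × het-AB × genotyping-rate filters evaluated by truth retention,
  truth-sample precision/recall and the transmitted/untransmitted
  synonymous singleton ratio (≈ 1 under unbiased calling).
* **Validation** — rare (< 0.1%) and ultra-rare (< 0.003% external)
  classification, high-confidence PTV calling, the per-sample burden score
  `S_het burden = 1 − ∏_g (1 − s_het,g)` over qualifying genes,
  covariate-adjusted association tests with a synonymous negative control,
  Fisher/regression comparisons of blood- versus cell-line-derived DNA,
  and exact Poisson genetic-prevalence estimation with a Garwood CI.

A fully labelled synthetic cohort generator (`simulate_cohort()` +
`inject_error_modes()`) provides Mendelian trios, ancestry structure, an
OxoG-style C>A/G>T batch artefact, contamination, swaps, duplicates and
cell-line somatic excess, so every stage is exercised against ground truth.

## Worked example

Simulate a cohort with an injected OxoG batch artefact, train the variant
quality forest, apply a stringent filter profile, and check the calibration
metrics against the generator's truth labels:

```r
library(exoqc)

cfg <- sim_config(n_families = 60, n_singletons = 40, n_sites = 6600, seed = 11,
                  oxog_rate = 60, n_artefact_sites = 700,
                  artefact_batch_fraction = 0.3)
sim <- inject_error_modes(simulate_cohort(cfg))

labels <- label_training_sites(sim$callset, sim$labels$variants$truth_set)
feat   <- extract_features(sim$callset)
scores <- train_and_score(feat, labels, sim$callset$variants$contig, seed = 5)
bins   <- bin_scores(scores, variant_keys(sim$callset))

stringent <- filter_profile("stringent",
  snv   = list(max_bin = 84, min_dp = 5,  min_gq = 15, min_het_ab = 0.2, min_rate = 0.5),
  indel = list(max_bin = 58, min_dp = 10, min_gq = 20, min_het_ab = 0.3, min_rate = 0.5))
ap  <- apply_profile(sim$callset, bins, stringent)
art <- sim$labels$variants$label == "artefact"

mean(!ap$variant_pass[art])                 # artefact removal
mean(ap$variant_pass[labels == "truth"])    # truth retention
tu_ratio(ap$callset, sim$pedigree, sim$annotation)
```

which prints:

```
artefact variants removed: 100.0%
truth variants retained:   92.3%
synonymous singleton T/U after filtering: 1.065 (49/46)
```

The forest pushes the injected C>A/G>T sites into the worst score bins, so
the stringent bin cutoff removes all of them while keeping 92% of the
truth-set variants, and the transmitted/untransmitted ratio of parental
synonymous singletons stays near 1 — filtering has not biased transmission.

The prevalence machinery is closed-form and worth seeing once:

```r
prevalence_test(17031, observed = 3, incidence = 1/2500)
#> Genetic prevalence: 3 observed vs 7 expected among 17031 children
#>   (incidence 0.0004; 95% CI 3-14; two-sided exact Poisson p = 0.1803)
```

Three observed recessive homozygotes against seven expected from a
1-in-2,500 incidence is comfortably inside the exact 95% interval: the
cohort's genetic prevalence is consistent with the population incidence.

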