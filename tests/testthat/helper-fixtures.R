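## Shared fixtures, built once per test run and cached across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (is.null(.fixture_cache[[name]])) assign(name, maker(), .fixture_cache)
  get(name, .fixture_cache)
}

## clean two-population cohort with panel samples
base_sim <- function() cached("base", function() {
  simulate_cohort(sim_config(n_families = 40, n_singletons = 20, n_panel = 60,
                             n_sites = 6000, seed = 7, fst = 0.15))
})

## cohort with an injected OxoG batch artefact (variant-QC scenarios)
artefact_sim <- function() cached("artefact", function() {
  inject_error_modes(simulate_cohort(sim_config(
    n_families = 60, n_singletons = 40, n_sites = 6600, seed = 11,
    oxog_rate = 60, n_artefact_sites = 700, artefact_batch_fraction = 0.3)))
})

## forest scores and bins for the artefact cohort
artefact_scores <- function() cached("artefact_scores", function() {
  sim <- artefact_sim()
  labs <- label_training_sites(sim$callset, sim$labels$variants$truth_set)
  feat <- extract_features(sim$callset)
  scores <- train_and_score(feat, labs, sim$callset$variants$contig, seed = 5)
  list(labels = labs, features = feat, scores = scores,
       bins = bin_scores(scores, variant_keys(sim$callset)))
})

## brute-force trio Mendelian-error count (independent of the generator)
count_mendel_errors <- function(callset, pedigree) {
  trios <- complete_trios(pedigree, callset$samples$sample_id)
  auto <- callset$variants$contig != "chrX"
  total <- 0L
  for (i in seq_len(nrow(trios))) {
    cg <- callset$GT[auto, trios$child[i]]
    mg <- callset$GT[auto, trios$mother[i]]
    fg <- callset$GT[auto, trios$father[i]]
    bad <- (mg == 0L & fg == 0L & cg > 0L) |
           (mg == 2L & fg == 2L & cg < 2L) |
           (mg == 0L & cg == 2L) | (fg == 0L & cg == 2L) |
           (mg == 2L & cg == 0L) | (fg == 2L & cg == 0L)
    total <- total + sum(bad, na.rm = TRUE)
  }
  total
}

## tiny hand-built callset for arithmetic cases
toy_callset <- function(gt, ref = NULL, alt = NULL, contig = "chr1",
                        dp = NULL, gq = NULL, ad = NULL, ...) {
  gt <- as.matrix(gt)
  n_var <- nrow(gt); n_samp <- ncol(gt)
  ids <- colnames(gt)
  if (is.null(ids)) ids <- paste0("S", seq_len(n_samp))
  colnames(gt) <- ids
  if (is.null(ref)) ref <- rep("A", n_var)
  if (is.null(alt)) alt <- rep("G", n_var)
  variants <- data.frame(contig = rep(contig, length.out = n_var),
                         pos = seq_len(n_var), ref = ref, alt = alt,
                         stringsAsFactors = FALSE, ...)
  Callset(data.frame(sample_id = ids, stringsAsFactors = FALSE),
          variants, gt, DP = dp, GQ = gq, AD_alt = ad)
}
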