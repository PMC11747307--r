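#' Label training sites for variant quality scoring
#'
#' A site is a **negative** when it fails any hard filter: `QD < 2`,
#' `FS > 60` or `MQ < 30` (strict inequalities; `FS = 60` does not fail).
#' A site is **truth** when it belongs to a supplied truth set and does not
#' fail the hard filters — a hard-filter failure overrides truth-set
#' membership, since such calls are deemed erroneous regardless of the
#' site's presence in external panels. Everything else is unlabelled.
#'
#' @param callset A [Callset].
#' @param truth_set_member logical vector per variant (membership in any
#'   external truth set).
#' @param qd_min,fs_max,mq_min hard-filter thresholds.
#' @return Character vector in `{truth, negative, unlabelled}`.
#' @export
label_training_sites <- function(callset, truth_set_member,
                                 qd_min = 2, fs_max = 60, mq_min = 30) {
  v <- callset$variants
  neg <- (!is.na(v$qd) & v$qd < qd_min) |
         (!is.na(v$fs) & v$fs > fs_max) |
         (!is.na(v$mq) & v$mq < mq_min)
  out <- rep("unlabelled", nrow(v))
  out[truth_set_member] <- "truth"
  out[neg] <- "negative"
  out
}

#' Extract the variant-level feature table for forest scoring
#'
#' Features: QD, mean heterozygous allele balance (`mean_het_ab`, averaged
#' over het carriers at the site), the C>A/G>T SNV indicator `is_ca`
#' (omitted when `use_is_ca = FALSE`, e.g. for batches sequenced after the
#' library-prep fix), SOR, variant type, ReadPosRankSum, split-multiallelic
#' flag, spanning-deletion flag, alt-allele count, MQ, MQRankSum, allele
#' type and the mixed-multiallelic flag. Missing numeric features are
#' median-imputed with an accompanying missingness indicator so absence
#' itself stays informative.
#'
#' @param callset A [Callset].
#' @param use_is_ca include the C>A/G>T indicator feature.
#' @return data.frame of features, one row per variant.
#' @export
extract_features <- function(callset, use_is_ca = TRUE) {
  v <- callset$variants
  ab <- allele_balance(callset)
  het <- !is.na(callset$GT) & callset$GT == 1L
  ab[!het] <- NA_real_
  mean_het_ab <- rowMeans(ab, na.rm = TRUE)
  mean_het_ab[is.nan(mean_het_ab)] <- NA_real_
  feat <- data.frame(
    qd = v$qd,
    mean_het_ab = mean_het_ab,
    sor = v$sor,
    variant_type = factor(v$variant_type),
    read_pos_rank_sum = v$read_pos_rank_sum,
    was_split = v$was_split,
    has_star = v$has_star,
    n_alt_alleles = v$n_alt_alleles,
    mq = v$mq,
    mq_rank_sum = v$mq_rank_sum,
    allele_type = factor(v$allele_type),
    was_mixed = v$was_mixed)
  if (use_is_ca) {
    feat$is_ca <- as.integer(v$variant_type == "snv" &
                             ((v$ref == "C" & v$alt == "A") |
                              (v$ref == "G" & v$alt == "T")))
  }
  for (nm in names(feat)) {
    x <- feat[[nm]]
    if (is.numeric(x) && anyNA(x)) {
      feat[[paste0(nm, "_missing")]] <- as.integer(is.na(x))
      med <- stats::median(x, na.rm = TRUE)
      x[is.na(x)] <- if (is.na(med)) 0 else med
      feat[[nm]] <- x
    }
  }
  feat
}

#' Train the variant-quality random forest and score all variants
#'
#' Trains a single probability forest (SNVs and indels together; the
#' variant/allele-type features let the trees split by class) on the
#' labelled truth/negative sites of one training contig and applies it to
#' every variant. Scores are the forest's truth-class probability in
#' `[0, 1]`, higher meaning more truth-like; a fixed seed makes them
#' reproducible.
#'
#' @param features data.frame from [extract_features()].
#' @param labels character vector from [label_training_sites()].
#' @param contigs contig per variant (used to pick training rows).
#' @param training_contig contig trained on (default `"chr20"`).
#' @param seed forest seed.
#' @param num_trees number of trees (default 500).
#' @return Numeric score per variant.
#' @export
train_and_score <- function(features, labels, contigs,
                            training_contig = "chr20", seed = 1L,
                            num_trees = 500) {
  tr <- contigs == training_contig & labels %in% c("truth", "negative")
  y <- factor(labels[tr], levels = c("negative", "truth"))
  if (length(unique(y)) < 2) {
    stop("training contig '", training_contig,
         "' does not contain both truth and negative sites")
  }
  ## balanced class weights: inverse class frequency
  tab <- table(y)
  wt <- stats::setNames(as.numeric(length(y) / (2 * tab)), names(tab))
  dat <- data.frame(.label = y, features[tr, , drop = FALSE])
  fit <- ranger::ranger(.label ~ ., data = dat, probability = TRUE,
                        num.trees = num_trees, seed = seed,
                        class.weights = as.numeric(wt[levels(y)]))
  pred <- stats::predict(fit, features)$predictions
  as.numeric(pred[, "truth"])
}

#' Percentile-bin forest scores
#'
#' Ranks variants by descending score and assigns near-equal-occupancy bins
#' `1..n_bins` (bin 1 = best). Ties break deterministically on the supplied
#' variant keys, so binning is stable across runs.
#'
#' @param scores numeric forest scores (finite).
#' @param keys variant keys used as the tie-break.
#' @param n_bins number of bins (default 100).
#' @return Integer bin per variant.
#' @export
bin_scores <- function(scores, keys, n_bins = 100) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  ord <- order(-scores, keys)
  bin <- integer(n)
  bin[ord] <- as.integer(floor((seq_len(n) - 1) * n_bins / n) + 1)
  bin
}

#' Cumulative truth/negative retention curves over score bins
#'
#' For each bin `b`, the percentage of all truth variants and of all
#' negative variants falling in bins `<= b`. Both curves are monotone
#' non-decreasing and reach 100% at the last bin.
#'
#' @param bins integer bins from [bin_scores()].
#' @param labels character labels from [label_training_sites()].
#' @param n_bins number of bins.
#' @return data.frame with `bin`, `truth_pct`, `negative_pct`.
#' @export
cumulative_tp_fp <- function(bins, labels, n_bins = 100) {
  cum_pct <- function(cls) {
    tot <- sum(labels == cls)
    cnt <- tabulate(bins[labels == cls], nbins = n_bins)
    if (tot == 0) rep(NA_real_, n_bins) else 100 * cumsum(cnt) / tot
  }
  data.frame(bin = seq_len(n_bins),
             truth_pct = cum_pct("truth"),
             negative_pct = cum_pct("negative"))
}

#' Define a variant-and-genotype filter profile
#'
#' A profile couples a variant-level forest-bin cutoff with genotype-level
#' DP/GQ/heterozygous-allele-balance thresholds and a minimum post-masking
#' genotyping rate, with separate settings for SNVs and indels.
#'
#' @param name profile name (e.g. relaxed/medium/stringent).
#' @param snv,indel named lists with `max_bin`, `min_dp`, `min_gq`,
#'   `min_het_ab`, `min_rate`.
#' @return List of class `filter_profile`.
#' @export
filter_profile <- function(name,
                           snv = list(max_bin = 84, min_dp = 5, min_gq = 15,
                                      min_het_ab = 0.2, min_rate = 0.5),
                           indel = list(max_bin = 58, min_dp = 10, min_gq = 20,
                                        min_het_ab = 0.3, min_rate = 0.5)) {
  need <- c("max_bin", "min_dp", "min_gq", "min_het_ab", "min_rate")
  for (part in list(snv, indel)) {
    if (!all(need %in% names(part))) {
      stop("profile parts need fields: ", paste(need, collapse = ", "))
    }
  }
  structure(list(name = name, snv = snv, indel = indel),
            class = "filter_profile")
}

#' Apply a filter profile to a callset
#'
#' Genotypes with DP, GQ or (het calls only) allele balance strictly below
#' the profile thresholds are set to missing; a variant passes if its
#' forest bin is `<= max_bin` and its post-masking genotyping rate is
#' `>= min_rate` (computed over all samples, after masking, before any
#' variant drop). The operation is idempotent.
#'
#' @param callset A [Callset].
#' @param bins integer forest bin per variant.
#' @param profile A [filter_profile()].
#' @return List with the masked `callset` restricted to passing variants,
#'   the logical `variant_pass` vector over the input variants, the
#'   genotype `mask` actually applied, and per-variant `genotyping_rate`.
#' @export
apply_profile <- function(callset, bins, profile) {
  v <- callset$variants
  is_snv <- v$variant_type == "snv"
  par_of <- function(field) ifelse(is_snv, profile$snv[[field]], profile$indel[[field]])
  ab <- allele_balance(callset)
  min_dp <- par_of("min_dp"); min_gq <- par_of("min_gq")
  min_ab <- par_of("min_het_ab")
  bad <- (!is.na(callset$DP) & callset$DP < min_dp) |
         (!is.na(callset$GQ) & callset$GQ < min_gq) |
         (!is.na(callset$GT) & callset$GT == 1L & !is.na(ab) & ab < min_ab)
  gt <- callset$GT
  gt[bad] <- NA_integer_
  rate <- rowMeans(!is.na(gt))
  pass <- bins <= par_of("max_bin") & rate >= par_of("min_rate")
  out <- callset
  out$GT <- gt
  out <- subset_callset(out, variants = which(pass))
  list(callset = out, variant_pass = pass, mask = bad,
       genotyping_rate = rate, bins = bins[pass])
}

#' Genotype pass flags for the three release profiles
#'
#' Computes, for each profile, a per-genotype indicator that the genotype
#' passes its thresholds *and* sits in a passing variant — the tri-level
#' flags written by [write_release_vcf()].
#'
#' @param callset A [Callset].
#' @param bins integer forest bin per variant.
#' @param profiles named list of three [filter_profile()]s
#'   (`relaxed`, `medium`, `stringent`).
#' @return Named list of logical matrices.
#' @export
profile_pass_flags <- function(callset, bins, profiles) {
  lapply(profiles, function(p) {
    ap <- apply_profile(callset, bins, p)
    flags <- !ap$mask & !is.na(callset$GT)
    flags[!ap$variant_pass, ] <- FALSE
    flags
  })
}

#' Transmitted/untransmitted ratio of parental singletons
#'
#' Over sites of the requested consequence class where the alternate allele
#' is seen in exactly one individual among all parents (a heterozygous
#' dataset singleton, under the default `among = "parents"`), that parent
#' belongs to a complete trio, and the child genotype is non-missing: the
#' allele is transmitted when the child carries it. Unbiased calling gives
#' a ratio near 1; a QC that preferentially masks child het calls drags it
#' below 1.
#'
#' @param callset A (possibly masked) [Callset].
#' @param pedigree A [Pedigree].
#' @param annotation data.frame with `key` and `consequence`.
#' @param class consequence class of qualifying sites.
#' @param among count the allele over `"parents"` (default) or
#'   `"all_samples"` — the latter is degenerate, since every transmitted
#'   allele is then no longer a singleton, and exists only for comparison.
#' @return List with `transmitted`, `untransmitted`, `ratio`
#'   (`NA` when no untransmitted events) and `pct_transmitted`.
#' @export
tu_ratio <- function(callset, pedigree, annotation, class = "synonymous",
                     among = c("parents", "all_samples")) {
  among <- match.arg(among)
  trios <- complete_trios(pedigree, callset$samples$sample_id)
  if (nrow(trios) == 0) stop("no complete trio in the callset")
  keys <- variant_keys(callset)
  csq <- annotation$consequence[match(keys, annotation$key)]
  vsel <- which(!is.na(csq) & csq == class)
  parent_ids <- unique(c(trios$mother, trios$father))
  count_cols <- if (among == "parents") parent_ids else callset$samples$sample_id
  gt_cnt <- callset$GT[vsel, count_cols, drop = FALSE]
  carriers <- rowSums(gt_cnt > 0L, na.rm = TRUE)
  ac <- rowSums(gt_cnt, na.rm = TRUE)
  single <- carriers == 1L & ac == 1L
  t_cnt <- 0L; u_cnt <- 0L
  gt_par <- callset$GT[vsel, parent_ids, drop = FALSE]
  for (i in which(single)) {
    carrier <- parent_ids[which(!is.na(gt_par[i, ]) & gt_par[i, ] == 1L)]
    if (length(carrier) != 1L) next
    tr <- trios[trios$mother == carrier | trios$father == carrier, , drop = FALSE]
    if (nrow(tr) != 1L) next            # carrier must be in exactly one trio
    child_gt <- callset$GT[vsel[i], tr$child]
    if (is.na(child_gt)) next
    if (child_gt > 0L) t_cnt <- t_cnt + 1L else u_cnt <- u_cnt + 1L
  }
  list(transmitted = t_cnt, untransmitted = u_cnt,
       ratio = if (u_cnt > 0) t_cnt / u_cnt else NA_real_,
       pct_transmitted = if (t_cnt + u_cnt > 0)
         100 * t_cnt / (t_cnt + u_cnt) else NA_real_)
}

#' Precision and recall against a truth sample
#'
#' Compares the retained non-reference genotypes of a benchmark sample
#' (GIAB-style) to its authoritative variant list. A retained call is a
#' true positive iff a truth entry with identical contig/pos/ref/alt
#' exists (zygosity ignored by default). Precision is `TP / (TP + FP)`
#' (`NA`-flagged for an empty retained set) and recall is
#' `TP / n_truth_entries`.
#'
#' @param callset the masked/filtered [Callset].
#' @param truth_keys character vector of truth variant keys
#'   (`contig:pos:ref:alt`), optionally named with truth genotypes (1/2)
#'   when `require_zygosity`.
#' @param truth_sample_id the benchmark sample's id in the callset.
#' @param require_zygosity also require the genotype class to match.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
truth_sample_eval <- function(callset, truth_keys, truth_sample_id,
                              require_zygosity = FALSE) {
  j <- match(truth_sample_id, callset$samples$sample_id)
  if (is.na(j)) stop("truth sample '", truth_sample_id, "' absent from callset")
  gt <- callset$GT[, j]
  called <- which(!is.na(gt) & gt > 0L)
  keys <- variant_keys(callset)[called]
  in_truth <- keys %in% truth_keys
  if (require_zygosity && !is.null(names(truth_keys))) {
    tz <- as.integer(names(truth_keys))[match(keys, truth_keys)]
    in_truth <- in_truth & !is.na(tz) & tz == gt[called]
  }
  tp <- sum(in_truth); fp <- sum(!in_truth)
  n_truth <- length(truth_keys)
  list(tp = tp, fp = fp, fn = n_truth - tp,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (n_truth > 0) tp / n_truth else NA_real_)
}

#' Evaluate a grid of candidate filter profiles
#'
#' Applies every candidate profile and reports the five selection metrics:
#' percentage of truth and of negative (training-label) variants retained,
#' precision and recall against the truth sample, and the
#' transmitted/untransmitted synonymous-singleton ratio. Profile choice
#' from the table is a human/config decision, not automated here.
#'
#' @param callset A [Callset].
#' @param bins forest bin per variant.
#' @param labels training labels per variant.
#' @param candidates list of [filter_profile()]s.
#' @param pedigree A [Pedigree] (optional; `NULL` skips the T/U column).
#' @param annotation annotation table for the T/U class (optional).
#' @param truth_keys,truth_sample_id truth-sample benchmark (optional).
#' @return data.frame, one row per candidate.
#' @export
evaluate_grid <- function(callset, bins, labels, candidates,
                          pedigree = NULL, annotation = NULL,
                          truth_keys = NULL, truth_sample_id = NULL) {
  rows <- lapply(candidates, function(p) {
    ap <- apply_profile(callset, bins, p)
    keep <- ap$variant_pass
    truth_total <- sum(labels == "truth")
    neg_total <- sum(labels == "negative")
    out <- data.frame(
      profile = p$name,
      snv_max_bin = p$snv$max_bin, snv_min_dp = p$snv$min_dp,
      snv_min_gq = p$snv$min_gq, snv_min_het_ab = p$snv$min_het_ab,
      snv_min_rate = p$snv$min_rate,
      pct_truth_retained = if (truth_total > 0)
        100 * sum(keep & labels == "truth") / truth_total else NA_real_,
      pct_negative_retained = if (neg_total > 0)
        100 * sum(keep & labels == "negative") / neg_total else NA_real_,
      precision = NA_real_, recall = NA_real_, tu = NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(truth_keys) && !is.null(truth_sample_id)) {
      ev <- truth_sample_eval(ap$callset, truth_keys, truth_sample_id)
      out$precision <- ev$precision; out$recall <- ev$recall
    }
    if (!is.null(pedigree) && !is.null(annotation) &&
        nrow(complete_trios(pedigree, callset$samples$sample_id)) > 0) {
      out$tu <- tu_ratio(ap$callset, pedigree, annotation)$ratio
    }
    out
  })
  do.call(rbind, rows)
}
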