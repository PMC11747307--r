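#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic site: given the minor-allele count,
#' sums the probabilities of heterozygote counts whose conditional
#' probability does not exceed that of the observed count (the standard
#' exact HWE formulation; mid-p off by default).
#'
#' @param n_het,n_hom_ref,n_hom_alt genotype counts.
#' @param midp halve the probability of the observed outcome.
#' @return Two-sided p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom_ref, n_hom_alt, midp = FALSE) {
  n <- n_het + n_hom_ref + n_hom_alt
  if (n == 0) return(NA_real_)
  n_a <- 2 * n_hom_alt + n_het            # alt allele count
  n_minor <- min(n_a, 2 * n - n_a)
  ## conditional log-probabilities of all feasible het counts (same parity
  ## as the minor-allele count)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  lp <- vapply(hets, function(h) {
    homa <- (n_minor - h) / 2
    homr <- n - h - homa
    lfactorial(n) - lfactorial(h) - lfactorial(homa) - lfactorial(homr) +
      h * log(2) + lfactorial(n_minor) + lfactorial(2 * n - n_minor) -
      lfactorial(2 * n)
  }, 0)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- min(n_het, n_minor)
  pi_obs <- p[match(obs, hets)]
  le <- p <= pi_obs * (1 + 1e-12)
  out <- sum(p[le])
  if (midp) out <- out - pi_obs / 2
  min(out, 1)
}

.PALINDROME <- c("A:T", "T:A", "C:G", "G:C")

#' Select variants for principal component analysis
#'
#' Restricts to autosomal biallelic SNVs intersected with the reference
#' panel's coordinates, then removes sites with call rate < 0.99, allele
#' frequency < 0.05, exact Hardy-Weinberg p < 1e-5, sites inside long-range
#' linkage-disequilibrium regions, and palindromic (A/T, C/G) SNVs. All
#' inequalities are strict, so a site at exactly the threshold is retained.
#'
#' @param callset A [Callset] (cohort merged with panel samples, or cohort
#'   only).
#' @param panel_variants data.frame with `contig`, `pos`, `ref`, `alt` of
#'   the panel sites (`NULL` to skip the intersection).
#' @param min_call_rate,min_af,min_hwe_p filter thresholds.
#' @param lrld_regions data.frame with `contig`, `start`, `end` (1-based,
#'   inclusive) exclusion regions; default from
#'   `system.file("extdata", "lrld_grch38.bed", package = "exoqc")`.
#' @return Integer vector of retained variant row indices.
#' @export
select_pca_variants <- function(callset, panel_variants = NULL,
                                min_call_rate = 0.99, min_af = 0.05,
                                min_hwe_p = 1e-5, lrld_regions = NULL) {
  v <- callset$variants
  keep <- v$contig %in% .AUTOSOMES & v$variant_type == "snv"
  keep <- keep & !(paste(v$ref, v$alt, sep = ":") %in% .PALINDROME)
  if (!is.null(panel_variants)) {
    pk <- paste(panel_variants$contig, panel_variants$pos,
                panel_variants$ref, panel_variants$alt, sep = ":")
    keep <- keep & variant_keys(callset) %in% pk
  }
  if (is.null(lrld_regions)) {
    bed <- system.file("extdata", "lrld_grch38.bed", package = "exoqc")
    if (nzchar(bed)) {
      lrld_regions <- utils::read.delim(bed, header = FALSE,
        col.names = c("contig", "start", "end"))
      lrld_regions$start <- lrld_regions$start + 1L   # BED is 0-based half-open
    }
  }
  if (!is.null(lrld_regions) && nrow(lrld_regions)) {
    for (i in seq_len(nrow(lrld_regions))) {
      keep <- keep & !(v$contig == lrld_regions$contig[i] &
                       v$pos >= lrld_regions$start[i] &
                       v$pos <= lrld_regions$end[i])
    }
  }
  fr <- site_frequencies(callset)
  keep <- keep & !is.na(fr$af) & fr$call_rate >= min_call_rate &
          pmin(fr$af, 1 - fr$af) >= min_af
  idx <- which(keep)
  if (length(idx)) {
    gt <- callset$GT[idx, , drop = FALSE]
    hwe_p <- vapply(seq_along(idx), function(i) {
      g <- gt[i, ]; g <- g[!is.na(g)]
      hwe_exact_test(sum(g == 1L), sum(g == 0L), sum(g == 2L))
    }, 0)
    idx <- idx[is.na(hwe_p) | hwe_p >= min_hwe_p]
  }
  if (!length(idx)) stop("no variants remain after PCA filtering (empty intersection?)")
  idx
}

#' Greedy windowed linkage-disequilibrium pruning
#'
#' Slides a window of `window` consecutive (position-sorted) variants with
#' step `step`; within each window, the later variant of any pair whose
#' squared genotype-dosage correlation exceeds `r2_max` is dropped. Kept
#' pairs within a window therefore never exceed the bound. Monomorphic
#' sites (undefined correlation) are treated as uncorrelated.
#'
#' @param gt genotype dosage matrix (variants x samples), position-sorted.
#' @param r2_max squared-correlation bound (default 0.2).
#' @param window window size in variants.
#' @param step step between window starts.
#' @return Integer vector of retained variant row indices.
#' @export
ld_prune <- function(gt, r2_max = 0.2, window = 50, step = ceiling(window / 2)) {
  n <- nrow(gt)
  if (n <= 1) return(seq_len(n))
  dropped <- rep(FALSE, n)
  starts <- seq(1, max(1, n - 1), by = step)
  for (s in starts) {
    e <- min(s + window - 1, n)
    idx <- s:e
    idx <- idx[!dropped[idx]]
    if (length(idx) < 2) next
    sub <- t(gt[idx, , drop = FALSE])
    r <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    r2 <- r^2
    for (a in seq_along(idx)) {
      if (dropped[idx[a]]) next
      for (b in seq_along(idx)) {
        if (b <= a || dropped[idx[b]]) next
        if (r2[a, b] > r2_max) dropped[idx[b]] <- TRUE
      }
    }
    if (e == n) break
  }
  which(!dropped)
}

#' Assign samples to continental populations by PCA
#'
#' Mean-imputes and standardizes genotype dosages of cohort plus panel
#' samples jointly, decomposes them by PCA (merged, not projected), trains a
#' probabilistic bagged-trees classifier on the panel's population labels
#' over the leading components, and predicts each cohort sample. Samples
#' whose maximum class probability falls below `min_prob` get the label
#' `"oth"`.
#'
#' @param callset A [Callset] already restricted to the PCA variant set
#'   (see [select_pca_variants()] and [ld_prune()]), containing both cohort
#'   and panel samples.
#' @param panel_ids sample ids of the labelled panel members.
#' @param panel_labels population label per panel id.
#' @param n_pcs number of leading components used (default 10).
#' @param min_prob assignment probability cutoff (default 0.9).
#' @param seed forest seed.
#' @param num_trees trees in the bagged classifier.
#' @return data.frame of class `ancestry_result`: ids, PC coordinates,
#'   predicted label (`"oth"` when unassignable) and assignment probability.
#' @export
assign_populations <- function(callset, panel_ids, panel_labels, n_pcs = 10,
                               min_prob = 0.9, seed = 1L, num_trees = 300) {
  if (length(unique(panel_labels)) < 2) {
    stop("need at least two panel populations")
  }
  X <- t(callset$GT)                     # samples x variants
  if (nrow(X) <= n_pcs) stop("fewer samples than requested components")
  n_pcs <- min(n_pcs, ncol(X))
  cm <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- cm[j]
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  X <- scale(X[, keep, drop = FALSE])
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(scores) <- callset$samples$sample_id
  pi <- match(panel_ids, callset$samples$sample_id)
  if (anyNA(pi)) stop("panel ids absent from callset: ",
                      paste(panel_ids[is.na(pi)], collapse = ", "))
  train <- data.frame(label = factor(panel_labels), scores[pi, , drop = FALSE])
  ## bagged trees with randomised split points (extra-trees) and pure
  ## leaves: samples inside a cluster are assigned with probability near 1,
  ## while points in the gap between clusters draw mixed votes and fall
  ## through to "oth" at the probability cutoff
  fit <- ranger::ranger(label ~ ., data = train, probability = TRUE,
                        num.trees = num_trees, seed = seed,
                        min.node.size = 1, mtry = n_pcs,
                        splitrule = "extratrees", num.random.splits = 1)
  pred <- stats::predict(fit, data.frame(scores))$predictions
  best <- max.col(pred)
  prob <- pred[cbind(seq_len(nrow(pred)), best)]
  label <- colnames(pred)[best]
  label[prob < min_prob] <- "oth"
  out <- data.frame(sample_id = callset$samples$sample_id,
                    predicted_pop = label, probability = prob,
                    stringsAsFactors = FALSE)
  colnames(scores) <- paste0("pc", seq_len(n_pcs))
  out <- cbind(out, as.data.frame(scores, row.names = NULL))
  class(out) <- c("ancestry_result", "data.frame")
  out
}
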