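#' Pre-filter genotypes before sample-metric calculation
#'
#' Sets to missing any genotype with total depth `DP < min_dp`, genotype
#' quality `GQ < min_gq`, or (heterozygous calls only) allele balance
#' `AB < min_het_ab`. Inequalities are strict: `DP = 20` passes at the
#' default threshold. The mask applies only to the returned copy; the input
#' callset is untouched. This pre-filter exists so that per-sample metrics
#' are not skewed by genotypes that would fail any reasonable genotype QC;
#' the formal genotype QC happens later in the filter grid.
#'
#' @param callset A [Callset] with `DP`, `GQ` and `AD_alt`.
#' @param min_dp,min_gq,min_het_ab thresholds (non-negative).
#' @return A masked copy of the callset.
#' @export
prefilter_genotypes <- function(callset, min_dp = 20, min_gq = 20,
                                min_het_ab = 0.25) {
  stopifnot(min_dp >= 0, min_gq >= 0, min_het_ab >= 0)
  ab <- allele_balance(callset)
  bad <- (!is.na(callset$DP) & callset$DP < min_dp) |
         (!is.na(callset$GQ) & callset$GQ < min_gq) |
         (!is.na(callset$GT) & callset$GT == 1L & !is.na(ab) & ab < min_het_ab)
  out <- callset
  out$GT[bad] <- NA_integer_
  out
}

.is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Per-sample quality metrics
#'
#' Counts of non-reference genotypes per sample after any pre-filtering:
#' SNVs, transitions (A<->G, C<->T), transversions, insertions, deletions,
#' and the Ti/Tv, insertion/deletion, het/hom ratios plus the
#' heterozygosity rate (het calls / non-missing calls). Ratios with a zero
#' denominator are reported as `NA` with the `ratio_undefined` flag set —
#' never as `Inf`. A sample with zero non-missing calls is flagged
#' `unevaluable`.
#'
#' @param callset A (typically pre-filtered) [Callset].
#' @return data.frame of metrics, one row per sample.
#' @export
compute_sample_metrics <- function(callset) {
  v <- callset$variants
  is_snv <- v$variant_type == "snv"
  is_ti <- is_snv & .is_transition(v$ref, v$alt)
  is_tv <- is_snv & !is_ti
  is_ins <- v$allele_type == "ins"
  is_del <- v$allele_type == "del"
  gt <- callset$GT
  nonref <- !is.na(gt) & gt > 0L
  het <- !is.na(gt) & gt == 1L
  homa <- !is.na(gt) & gt == 2L
  cnt <- function(mask) colSums(nonref & mask)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  n_nonmiss <- colSums(!is.na(gt))
  out <- data.frame(
    sample_id = callset$samples$sample_id,
    n_nonmissing = n_nonmiss,
    n_snv = cnt(is_snv),
    n_transition = cnt(is_ti),
    n_transversion = cnt(is_tv),
    n_insertion = cnt(is_ins),
    n_deletion = cnt(is_del),
    n_het = colSums(het),
    n_hom_alt = colSums(homa),
    stringsAsFactors = FALSE)
  out$ti_tv_ratio <- ratio(out$n_transition, out$n_transversion)
  out$ins_del_ratio <- ratio(out$n_insertion, out$n_deletion)
  out$het_hom_ratio <- ratio(out$n_het, out$n_hom_alt)
  out$het_rate <- ratio(out$n_het, out$n_nonmissing)
  out$ratio_undefined <- out$n_transversion == 0 | out$n_deletion == 0 |
    out$n_hom_alt == 0
  out$unevaluable <- n_nonmiss == 0L
  rownames(out) <- NULL
  out
}

#' Flag outlier samples by stratified median/MAD bounds
#'
#' For each metric and stratum (cohort x inferred population), a sample
#' fails if its value falls strictly outside `median +/- k * MAD`, where MAD
#' is the raw median absolute deviation (no Gaussian consistency factor —
#' the `mad_constant` argument exposes it). `NA` metric values are excluded
#' from bounds and never flagged. In a stratum where all values are equal
#' (MAD 0), an epsilon half-width (`mad_epsilon`, default 0 widened to treat
#' equal-valued strata as outlier-free) prevents flagging the whole stratum.
#' Strata smaller than `min_stratum` are not flagged, with a warning.
#'
#' @param metrics data.frame from [compute_sample_metrics()].
#' @param strata character vector of stratum labels, one per sample.
#' @param k half-width in MADs (default 4).
#' @param metric_cols metric columns to screen.
#' @param mad_constant scale factor passed to [stats::mad()] (default 1).
#' @param mad_epsilon minimum half-width when MAD is zero; `Inf`-free
#'   default 0 means equal-valued strata flag nothing because the bounds
#'   collapse to the shared value itself.
#' @param min_stratum minimum stratum size for flagging.
#' @return List of class `outlier_report`: `bounds` (per metric/stratum) and
#'   `flags` (per sample: failed metrics and union fail flag).
#' @export
flag_outliers <- function(metrics, strata, k = 4,
                          metric_cols = c("n_snv", "n_transition",
                                          "n_transversion", "ti_tv_ratio",
                                          "n_insertion", "n_deletion",
                                          "ins_del_ratio", "het_hom_ratio",
                                          "het_rate"),
                          mad_constant = 1, mad_epsilon = 0,
                          min_stratum = 10) {
  stopifnot(length(strata) == nrow(metrics))
  bounds <- list()
  fail <- matrix(FALSE, nrow(metrics), length(metric_cols),
                 dimnames = list(metrics$sample_id, metric_cols))
  for (s in unique(strata)) {
    in_s <- strata == s
    if (sum(in_s) < min_stratum) {
      warning("stratum '", s, "' has fewer than ", min_stratum,
              " samples; not flagged")
      next
    }
    for (mc in metric_cols) {
      v <- metrics[[mc]][in_s]
      v_ok <- v[!is.na(v)]
      if (!length(v_ok)) next
      med <- stats::median(v_ok)
      mad_v <- stats::mad(v_ok, constant = mad_constant)
      half <- max(k * mad_v, mad_epsilon)
      lo <- med - half; hi <- med + half
      bounds[[length(bounds) + 1L]] <- data.frame(
        stratum = s, metric = mc, median = med, mad = mad_v,
        lower = lo, upper = hi, stringsAsFactors = FALSE)
      fail[in_s, mc] <- !is.na(v) & (v < lo | v > hi)
    }
  }
  flags <- data.frame(
    sample_id = metrics$sample_id,
    failed_metrics = apply(fail, 1, function(r)
      paste(metric_cols[r], collapse = ",")),
    fail = rowSums(fail) > 0,
    stringsAsFactors = FALSE)
  rownames(flags) <- NULL
  structure(list(bounds = if (length(bounds)) do.call(rbind, bounds)
                 else data.frame(),
                 flags = flags),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Outlier report:", sum(x$flags$fail), "of", nrow(x$flags),
      "samples flagged\n")
  invisible(x)
}

#' Contamination screen on free-mix scores
#'
#' Samples with a free-mix (estimated cross-sample contamination fraction)
#' score strictly above the threshold are removed or flagged depending on
#' policy; a score of exactly the threshold passes. Missing scores are
#' `unevaluable`. Both score and decision are returned for logging.
#'
#' @param samples data.frame with `sample_id` and `free_mix`.
#' @param threshold free-mix cutoff (default 0.05).
#' @param policy `"remove"` or `"flag"`.
#' @return data.frame with `sample_id`, `free_mix`, `decision` in
#'   `{keep, flag, remove, unevaluable}`.
#' @export
screen_contamination <- function(samples, threshold = 0.05,
                                 policy = c("remove", "flag")) {
  policy <- match.arg(policy)
  sc <- samples$free_mix
  if (any(!is.na(sc) & (sc < 0 | sc > 1))) stop("free-mix scores must be in [0, 1]")
  decision <- ifelse(is.na(sc), "unevaluable",
              ifelse(sc > threshold, ifelse(policy == "remove", "remove", "flag"),
                     "keep"))
  data.frame(sample_id = samples$sample_id, free_mix = sc,
             decision = decision, stringsAsFactors = FALSE)
}

#' Infer genetic sex from X heterozygosity and Y coverage
#'
#' X-chromosome variants are filtered to internal allele frequency >=
#' `min_af` and call rate >= `min_call_rate`; per sample the X inbreeding
#' coefficient is `F = (O_hom - E_hom) / (n - E_hom)` with the expected
#' homozygote count from (optionally stratum-specific) allele frequencies.
#' Samples with `F` near 1 and high normalized Y depth are called XY; both
#' low, XX; anything else (or no usable X variants) is `undetermined`, never
#' guessed. Fixed thresholds rather than fitted clusters keep the assignment
#' reproducible.
#'
#' @param callset A [Callset] whose `samples` carry a `y_depth` column
#'   (normalized Y coverage).
#' @param strata optional per-sample stratum labels for the allele
#'   frequencies used in the expectation.
#' @param min_af,min_call_rate X-variant filters.
#' @param f_xy,y_xy lower bounds of F and Y depth for an XY call.
#' @param f_xx,y_xx upper bounds of F and Y depth for an XX call.
#' @return data.frame with `sample_id`, `f_x`, `y_depth`, `inferred_sex` in
#'   `{XX, XY, undetermined}`.
#' @export
infer_sex <- function(callset, strata = NULL, min_af = 0.01,
                      min_call_rate = 0.99,
                      f_xy = 0.8, y_xy = 0.3, f_xx = 0.2, y_xx = 0.1) {
  n_samp <- nrow(callset$samples)
  y_depth <- callset$samples$y_depth
  if (is.null(y_depth)) y_depth <- rep(NA_real_, n_samp)
  on_x <- callset$variants$contig %in% c("chrX", "X")
  res <- data.frame(sample_id = callset$samples$sample_id,
                    f_x = NA_real_, y_depth = y_depth,
                    inferred_sex = "undetermined", stringsAsFactors = FALSE)
  if (!any(on_x)) return(res)
  xs <- subset_callset(callset, variants = which(on_x))
  fr <- site_frequencies(xs)
  keep <- !is.na(fr$af) & fr$af >= min_af & fr$af <= 1 - min_af &
          fr$call_rate >= min_call_rate
  if (!any(keep)) return(res)
  xs <- subset_callset(xs, variants = which(keep))
  if (is.null(strata)) strata <- rep("all", n_samp)
  for (s in unique(strata)) {
    si <- which(strata == s)
    gt <- xs$GT[, si, drop = FALSE]
    p <- site_frequencies(xs, samples = si)$af
    e_het <- 2 * p * (1 - p)
    for (jj in seq_along(si)) {
      ok <- !is.na(gt[, jj]) & !is.na(p)
      n <- sum(ok)
      if (n == 0) next
      o_hom <- sum(gt[ok, jj] != 1L)
      e_hom <- sum(1 - e_het[ok])
      denom <- n - e_hom
      res$f_x[si[jj]] <- if (abs(denom) < 1e-12) NA_real_ else (o_hom - e_hom) / denom
    }
  }
  f <- res$f_x; y <- res$y_depth
  res$inferred_sex[!is.na(f) & !is.na(y) & f > f_xy & y > y_xy] <- "XY"
  res$inferred_sex[!is.na(f) & !is.na(y) & f < f_xx & y < y_xx] <- "XX"
  res
}
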