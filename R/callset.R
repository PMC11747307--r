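#' Callset: the central genotype container
#'
#' A `Callset` holds a multi-sample variant callset after multiallelic
#' splitting: one row per biallelic record, one column per sample. Genotypes
#' are stored as alternate-allele dosages (0 = hom-ref, 1 = het, 2 = hom-alt,
#' `NA` = missing) together with per-genotype depth (`DP`), genotype quality
#' (`GQ`) and alternate-allele depth (`AD_alt`). Site-level quality
#' annotations (QD, FS, SOR, MQ, rank sums, allele-structure flags) live in
#' the `variants` table; per-sample metadata (cohort, batch, DNA source,
#' reported sex, free-mix contamination score, lane metrics) in `samples`.
#'
#' @param samples data.frame with at least a `sample_id` column (unique ids).
#' @param variants data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`; site annotation columns (`qd`, `fs`, `sor`, `mq`, `mq_rank_sum`,
#'   `read_pos_rank_sum`, `variant_type`, `allele_type`, `was_split`,
#'   `was_mixed`, `has_star`, `n_alt_alleles`) are optional and filled with
#'   `NA`/defaults when absent.
#' @param GT integer matrix (variants x samples) of dosages in `{0,1,2,NA}`.
#' @param DP,GQ,AD_alt optional integer matrices of the same shape.
#' @return An object of class `Callset`.
#' @export
Callset <- function(samples, variants, GT, DP = NULL, GQ = NULL, AD_alt = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(samples$sample_id)) stop("samples must have a 'sample_id' column")
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  req <- c("contig", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants table missing column(s): ", paste(miss, collapse = ", "))
  ann_num <- c("qd", "fs", "sor", "mq", "mq_rank_sum", "read_pos_rank_sum")
  for (a in ann_num) if (is.null(variants[[a]])) variants[[a]] <- NA_real_
  if (is.null(variants$variant_type)) {
    variants$variant_type <- ifelse(nchar(variants$ref) == 1L & nchar(variants$alt) == 1L,
                                    "snv", "indel")
  }
  if (is.null(variants$allele_type)) {
    variants$allele_type <- ifelse(nchar(variants$ref) == 1L & nchar(variants$alt) == 1L, "snv",
                            ifelse(nchar(variants$alt) > nchar(variants$ref), "ins", "del"))
  }
  for (a in c("was_split", "was_mixed", "has_star")) {
    if (is.null(variants[[a]])) variants[[a]] <- 0L
  }
  if (is.null(variants$n_alt_alleles)) variants$n_alt_alleles <- 1L
  GT <- as.matrix(GT)
  storage.mode(GT) <- "integer"
  if (nrow(GT) != nrow(variants) || ncol(GT) != nrow(samples)) {
    stop("GT must be n_variants x n_samples (", nrow(variants), " x ", nrow(samples), ")")
  }
  if (any(GT[!is.na(GT)] < 0L | GT[!is.na(GT)] > 2L)) stop("GT entries must be in {0,1,2,NA}")
  chk <- function(m, nm) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (!all(dim(m) == dim(GT))) stop(nm, " must have the same shape as GT")
    m
  }
  colnames(GT) <- samples$sample_id
  obj <- structure(list(samples = samples, variants = variants, GT = GT,
                        DP = chk(DP, "DP"), GQ = chk(GQ, "GQ"),
                        AD_alt = chk(AD_alt, "AD_alt")),
                   class = "Callset")
  obj
}

#' @export
print.Callset <- function(x, ...) {
  cat("Callset:", nrow(x$variants), "variants x", nrow(x$samples), "samples\n")
  cat("  contigs:", paste(unique(x$variants$contig)[1:min(6, length(unique(x$variants$contig)))],
                          collapse = ", "),
      if (length(unique(x$variants$contig)) > 6) "..." else "", "\n")
  cat("  genotype fields:",
      paste(c("GT", "DP", "GQ", "AD_alt")[!vapply(x[c("GT", "DP", "GQ", "AD_alt")], is.null, TRUE)],
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.Callset <- function(x) c(nrow(x$variants), nrow(x$samples))

#' Variant keys
#'
#' Canonical `contig:pos:ref:alt` key per record; used for joins with
#' annotation tables, truth sets and QC records.
#' @param callset A [Callset].
#' @return Character vector of keys.
#' @export
variant_keys <- function(callset) {
  with(callset$variants, paste(contig, pos, ref, alt, sep = ":"))
}

#' Heterozygous allele balance
#'
#' Alternate-allele read fraction `AD_alt / DP`, defined only for non-missing
#' genotypes with `DP > 0`; everything else is `NA`. With split multiallelic
#' records the denominator is total depth, i.e. other alleles are ignored.
#' @param callset A [Callset] carrying `DP` and `AD_alt`.
#' @return Numeric matrix (variants x samples).
#' @export
allele_balance <- function(callset) {
  if (is.null(callset$DP) || is.null(callset$AD_alt)) {
    stop("allele balance needs DP and AD_alt")
  }
  ab <- callset$AD_alt / callset$DP
  ab[is.na(callset$GT) | is.na(callset$DP) | callset$DP == 0L] <- NA_real_
  ab
}

#' Subset a callset
#'
#' @param callset A [Callset].
#' @param variants logical/integer index over variant rows (optional).
#' @param samples logical/integer index or character sample ids (optional).
#' @return A [Callset] restricted to the selection.
#' @export
subset_callset <- function(callset, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(nrow(callset$variants)) else variants
  si <- if (is.null(samples)) seq_len(nrow(callset$samples)) else samples
  if (is.character(si)) si <- match(si, callset$samples$sample_id)
  take <- function(m) if (is.null(m)) NULL else m[vi, si, drop = FALSE]
  Callset(samples = callset$samples[si, , drop = FALSE],
          variants = callset$variants[vi, , drop = FALSE],
          GT = callset$GT[vi, si, drop = FALSE],
          DP = take(callset$DP), GQ = take(callset$GQ), AD_alt = take(callset$AD_alt))
}

#' Internal allele frequency and call rate
#'
#' Alternate allele frequency and genotype call rate per variant, computed
#' over a chosen sample subset (e.g. unrelated probands for rarity
#' classification).
#' @param callset A [Callset].
#' @param samples optional sample ids or index; defaults to all samples.
#' @return data.frame with `af` and `call_rate` per variant.
#' @export
site_frequencies <- function(callset, samples = NULL) {
  gt <- callset$GT
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, callset$samples$sample_id) else samples
    gt <- gt[, si, drop = FALSE]
  }
  n_ok <- rowSums(!is.na(gt))
  ac <- rowSums(gt, na.rm = TRUE)
  data.frame(af = ifelse(n_ok > 0, ac / (2 * n_ok), NA_real_),
             call_rate = n_ok / ncol(gt))
}

#' Pedigree of declared family relationships
#'
#' One row per individual; `father_id`/`mother_id` are `NA` for founders.
#' `twin_group` marks monozygotic twin sets (shared non-`NA` value).
#'
#' @param family_id,individual_id,father_id,mother_id,role character vectors;
#'   `role` in `{child, mother, father}`.
#' @param twin_group optional character vector (NA = not a twin).
#' @return data.frame of class `Pedigree`.
#' @export
Pedigree <- function(family_id, individual_id, father_id = NA_character_,
                     mother_id = NA_character_, role = "child",
                     twin_group = NA_character_) {
  ped <- data.frame(family_id = family_id, individual_id = individual_id,
                    father_id = father_id, mother_id = mother_id,
                    role = role, twin_group = twin_group,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$individual_id)) stop("pedigree individual ids must be unique")
  bad <- !is.na(ped$father_id) & ped$father_id == ped$individual_id |
         !is.na(ped$mother_id) & ped$mother_id == ped$individual_id
  if (any(bad)) stop("individual cannot be its own parent")
  class(ped) <- c("Pedigree", "data.frame")
  ped
}

#' Complete trios in a pedigree
#'
#' A trio is complete iff child, mother and father are all present among the
#' supplied sample ids.
#' @param pedigree A [Pedigree].
#' @param sample_ids sample ids present in the callset.
#' @return data.frame with columns `child`, `mother`, `father`.
#' @export
complete_trios <- function(pedigree, sample_ids) {
  kids <- pedigree[!is.na(pedigree$father_id) & !is.na(pedigree$mother_id), , drop = FALSE]
  ok <- kids$individual_id %in% sample_ids &
        kids$father_id %in% sample_ids &
        kids$mother_id %in% sample_ids
  data.frame(child = kids$individual_id[ok], mother = kids$mother_id[ok],
             father = kids$father_id[ok], stringsAsFactors = FALSE)
}

#' First-degree pairs declared in a pedigree
#'
#' Parent-offspring pairs plus full siblings (children sharing both declared
#' parents). Monozygotic twins are a special case of siblings and keep their
#' `twin_group` tag.
#' @param pedigree A [Pedigree].
#' @return data.frame with `id1`, `id2`, `relation` in
#'   `{parent_offspring, full_sib}` and `mz_twin` logical.
#' @export
declared_first_degree <- function(pedigree) {
  out <- list()
  kids <- pedigree[!is.na(pedigree$father_id) | !is.na(pedigree$mother_id), , drop = FALSE]
  for (i in seq_len(nrow(kids))) {
    for (p in c(kids$father_id[i], kids$mother_id[i])) {
      if (!is.na(p)) {
        out[[length(out) + 1L]] <- data.frame(id1 = kids$individual_id[i], id2 = p,
                                              relation = "parent_offspring",
                                              mz_twin = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (nrow(kids) > 1) {
    key <- paste(kids$father_id, kids$mother_id)
    for (k in unique(key[duplicated(key)])) {
      sib <- kids$individual_id[key == k]
      tw <- kids$twin_group[key == k]
      cmb <- utils::combn(seq_along(sib), 2)
      for (j in seq_len(ncol(cmb))) {
        a <- cmb[1, j]; b <- cmb[2, j]
        out[[length(out) + 1L]] <- data.frame(
          id1 = sib[a], id2 = sib[b], relation = "full_sib",
          mz_twin = !is.na(tw[a]) && !is.na(tw[b]) && tw[a] == tw[b],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id1 = character(), id2 = character(),
                      relation = character(), mz_twin = logical()))
  }
  do.call(rbind, out)
}
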