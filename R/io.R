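## VCF-facing I/O. Reading goes through vcfR; writing assembles a vcfR
## object so headers and body stay consistent. INFO keys absent at a site
## round-trip as missing (VCF "."), never as zero: rank-sum annotations are
## legitimately absent at sites with no heterozygous carriers.

.INFO_KEYS <- c(QD = "qd", FS = "fs", SOR = "sor", MQ = "mq",
                MQRankSum = "mq_rank_sum", ReadPosRankSum = "read_pos_rank_sum")
.INFO_STR <- c(VARIANT_TYPE = "variant_type", ALLELE_TYPE = "allele_type")
.INFO_INT <- c(WAS_SPLIT = "was_split", WAS_MIXED = "was_mixed",
               HAS_STAR = "has_star", N_ALT_ALLELES = "n_alt_alleles")

.gt_string <- function(gt) {
  out <- rep("./.", length(gt))
  out[!is.na(gt) & gt == 0L] <- "0/0"
  out[!is.na(gt) & gt == 1L] <- "0/1"
  out[!is.na(gt) & gt == 2L] <- "1/1"
  out
}

.info_field <- function(variants) {
  n <- nrow(variants)
  parts <- matrix("", n, length(.INFO_KEYS) + length(.INFO_STR) + length(.INFO_INT))
  j <- 0L
  for (k in names(.INFO_KEYS)) {
    j <- j + 1L
    v <- variants[[.INFO_KEYS[[k]]]]
    parts[, j] <- ifelse(is.na(v), "", paste0(k, "=", sprintf("%.6g", v)))
  }
  for (k in names(.INFO_STR)) {
    j <- j + 1L
    v <- variants[[.INFO_STR[[k]]]]
    parts[, j] <- ifelse(is.na(v), "", paste0(k, "=", v))
  }
  for (k in names(.INFO_INT)) {
    j <- j + 1L
    v <- variants[[.INFO_INT[[k]]]]
    parts[, j] <- ifelse(is.na(v), "", paste0(k, "=", as.integer(v)))
  }
  apply(parts, 1, function(r) {
    r <- r[r != ""]
    if (!length(r)) "." else paste(r, collapse = ";")
  })
}

.vcf_meta <- function(contigs, extra_info = character(), extra_format = character()) {
  c("##fileformat=VCFv4.2",
    "##source=exoqc",
    paste0("##contig=<ID=", contigs, ">"),
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality normalised by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="FisherStrand phred p-value">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="Strand odds ratio">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mean mapping quality">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Rank sum of REF vs ALT mapping qualities">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Rank sum of REF vs ALT read positions">',
    '##INFO=<ID=VARIANT_TYPE,Number=1,Type=String,Description="snv or indel">',
    '##INFO=<ID=ALLELE_TYPE,Number=1,Type=String,Description="snv, ins or del">',
    '##INFO=<ID=WAS_SPLIT,Number=1,Type=Integer,Description="Record came from a split multiallelic site">',
    '##INFO=<ID=WAS_MIXED,Number=1,Type=Integer,Description="Multiallelic site mixed SNV and indel">',
    '##INFO=<ID=HAS_STAR,Number=1,Type=Integer,Description="Site overlaps a spanning deletion">',
    '##INFO=<ID=N_ALT_ALLELES,Number=1,Type=Integer,Description="Alt alleles at the original site">',
    extra_info,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    extra_format)
}

.assemble_gt <- function(callset, extra_format_keys = character(),
                         extra_format_vals = NULL) {
  n_var <- nrow(callset$variants); n_samp <- nrow(callset$samples)
  has_dp <- !is.null(callset$DP); has_gq <- !is.null(callset$GQ)
  has_ad <- !is.null(callset$AD_alt) && has_dp
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ", if (has_ad) "AD",
                 extra_format_keys), collapse = ":")
  body <- matrix("", n_var, n_samp)
  for (j in seq_len(n_samp)) {
    cell <- .gt_string(callset$GT[, j])
    if (has_dp) cell <- paste(cell, ifelse(is.na(callset$DP[, j]), ".", callset$DP[, j]), sep = ":")
    if (has_gq) cell <- paste(cell, ifelse(is.na(callset$GQ[, j]), ".", callset$GQ[, j]), sep = ":")
    if (has_ad) {
      ref_d <- callset$DP[, j] - callset$AD_alt[, j]
      cell <- paste(cell, ifelse(is.na(callset$AD_alt[, j]) | is.na(callset$DP[, j]), ".",
                                 paste0(ref_d, ",", callset$AD_alt[, j])), sep = ":")
    }
    if (!is.null(extra_format_vals)) {
      for (m in extra_format_vals) cell <- paste(cell, m[, j], sep = ":")
    }
    body[, j] <- cell
  }
  gt <- cbind(FORMAT = fmt, body)
  colnames(gt) <- c("FORMAT", callset$samples$sample_id)
  gt
}

.as_vcfR <- function(callset, extra_info_meta = character(),
                     extra_format_meta = character(),
                     info_extra = NULL, extra_format_keys = character(),
                     extra_format_vals = NULL) {
  info <- .info_field(callset$variants)
  if (!is.null(info_extra)) {
    info <- ifelse(info == ".", info_extra, paste(info, info_extra, sep = ";"))
  }
  fix <- cbind(CHROM = callset$variants$contig,
               POS = as.character(callset$variants$pos),
               ID = ".", REF = callset$variants$ref, ALT = callset$variants$alt,
               QUAL = ".", FILTER = ".", INFO = info)
  gt <- .assemble_gt(callset, extra_format_keys, extra_format_vals)
  methods::new("vcfR",
               meta = .vcf_meta(unique(callset$variants$contig),
                                extra_info_meta, extra_format_meta),
               fix = fix, gt = gt)
}

#' Write a callset as a multi-sample VCF
#'
#' @param callset A [Callset].
#' @param path output path (".vcf.gz" appended if absent; the file is
#'   gzip-compressed).
#' @return The path, invisibly.
#' @export
write_callset_vcf <- function(callset, path) {
  if (!grepl("\\.vcf\\.gz$", path)) path <- paste0(path, ".vcf.gz")
  vcfR::write.vcf(.as_vcfR(callset), file = path)
  invisible(path)
}

#' Read a multi-sample VCF plus sample metadata into a Callset
#'
#' Maps the GT/DP/GQ/AD FORMAT fields and the QD/FS/SOR/MQ/MQRankSum/
#' ReadPosRankSum/VARIANT_TYPE/ALLELE_TYPE/WAS_SPLIT/WAS_MIXED/HAS_STAR/
#' N_ALT_ALLELES INFO keys. Absent annotations are recorded as missing,
#' never as zero.
#'
#' @param vcf_path path to a VCF (plain or gzipped).
#' @param metadata_path optional tab-separated per-sample metadata with a
#'   `sample_id` column covering every VCF sample.
#' @return A [Callset].
#' @export
read_callset <- function(vcf_path, metadata_path = NULL) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                  error = function(e) stop("VCF parse error in '", vcf_path,
                                           "': ", conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  variants <- data.frame(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  for (k in names(.INFO_KEYS)) {
    variants[[.INFO_KEYS[[k]]]] <- suppressWarnings(
      vcfR::extract.info(vcf, element = k, as.numeric = TRUE))
  }
  for (k in names(.INFO_STR)) {
    variants[[.INFO_STR[[k]]]] <- vcfR::extract.info(vcf, element = k)
  }
  for (k in names(.INFO_INT)) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = k, as.numeric = TRUE))
    variants[[.INFO_INT[[k]]]] <- as.integer(v)
  }
  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  GT <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr), dimnames = dimnames(gt_chr))
  GT[gt_chr %in% c("0/0", "0|0")] <- 0L
  GT[gt_chr %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  GT[gt_chr %in% c("1/1", "1|1")] <- 2L
  DP <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  GQ <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  ad_chr <- vcfR::extract.gt(vcf, element = "AD")
  AD_alt <- NULL
  if (!all(is.na(ad_chr))) {
    AD_alt <- suppressWarnings(
      matrix(as.integer(vapply(strsplit(ad_chr, ","), function(x)
        if (length(x) >= 2) x[2] else NA_character_, "")),
        nrow(ad_chr), ncol(ad_chr), dimnames = dimnames(ad_chr)))
  }
  samp_ids <- colnames(gt_chr)
  samples <- data.frame(sample_id = samp_ids, stringsAsFactors = FALSE)
  if (!is.null(metadata_path)) {
    meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
    if (is.null(meta$sample_id)) stop("metadata must have a 'sample_id' column")
    missing_meta <- setdiff(samp_ids, meta$sample_id)
    if (length(missing_meta)) {
      stop("metadata/sample reconciliation error; VCF samples without metadata: ",
           paste(missing_meta, collapse = ", "))
    }
    samples <- meta[match(samp_ids, meta$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  if (all(is.na(DP))) DP <- NULL
  if (all(is.na(GQ))) GQ <- NULL
  Callset(samples, variants, GT, DP = DP, GQ = GQ, AD_alt = AD_alt)
}

#' Write the annotated release VCF
#'
#' Follows the released-data convention: genotypes are never modified or
#' dropped; instead the INFO field carries, per variant, the percentage of
#' samples passing each of the relaxed/medium/stringent profiles, and the
#' FORMAT field carries a per-genotype 0/1 pass indicator for each profile.
#'
#' @param callset A [Callset].
#' @param pass_flags named list of three logical matrices (variants x
#'   samples) named `relaxed`, `medium`, `stringent`.
#' @param path output path (gzip VCF).
#' @param info_keys,format_keys INFO/FORMAT key names for the three profiles
#'   (release key names are configurable).
#' @return The path, invisibly.
#' @export
write_release_vcf <- function(callset, pass_flags, path,
                              info_keys = c("PCT_PASS_RELAXED", "PCT_PASS_MEDIUM",
                                            "PCT_PASS_STRINGENT"),
                              format_keys = c("PASS_RELAXED", "PASS_MEDIUM",
                                              "PASS_STRINGENT")) {
  need <- c("relaxed", "medium", "stringent")
  if (!all(need %in% names(pass_flags))) {
    stop("pass_flags must contain matrices named: ", paste(need, collapse = ", "))
  }
  for (nm in need) {
    if (!all(dim(pass_flags[[nm]]) == dim(callset$GT))) {
      stop("pass_flags$", nm, " must match the callset dimensions")
    }
  }
  pct <- lapply(need, function(nm) 100 * rowMeans(pass_flags[[nm]]))
  info_extra <- paste(paste0(info_keys[1], "=", sprintf("%.4g", pct[[1]])),
                      paste0(info_keys[2], "=", sprintf("%.4g", pct[[2]])),
                      paste0(info_keys[3], "=", sprintf("%.4g", pct[[3]])),
                      sep = ";")
  fmt_vals <- lapply(need, function(nm) {
    m <- pass_flags[[nm]]
    matrix(as.character(as.integer(m)), nrow(m), ncol(m))
  })
  extra_info_meta <- paste0("##INFO=<ID=", info_keys,
    ',Number=1,Type=Float,Description="Percent of samples passing the ',
    need, ' profile">')
  extra_format_meta <- paste0("##FORMAT=<ID=", format_keys,
    ',Number=1,Type=Integer,Description="Genotype passes the ', need,
    ' profile">')
  obj <- .as_vcfR(callset, extra_info_meta, extra_format_meta,
                  info_extra = info_extra, extra_format_keys = format_keys,
                  extra_format_vals = fmt_vals)
  if (!grepl("\\.vcf\\.gz$", path)) path <- paste0(path, ".vcf.gz")
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the standard file set: gzipped multi-sample VCF, PED-format
#' pedigree (with a seventh twin-group column), tab-separated sample
#' metadata, truth labels and the variant annotation table.
#'
#' @param sim A `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "cohort.vcf.gz"),
             ped = file.path(dir, "cohort.ped"),
             samples = file.path(dir, "samples.tsv"),
             truth_variants = file.path(dir, "truth_variants.tsv"),
             truth_samples = file.path(dir, "truth_samples.tsv"),
             annotation = file.path(dir, "annotation.tsv"))
  write_callset_vcf(sim$callset, paths["vcf"])
  ped <- sim$pedigree
  sex_code <- ifelse(sim$callset$samples$sex[match(ped$individual_id,
                     sim$callset$samples$sample_id)] == "M", 1L, 2L)
  utils::write.table(
    data.frame(ped$family_id, ped$individual_id,
               ifelse(is.na(ped$father_id), "0", ped$father_id),
               ifelse(is.na(ped$mother_id), "0", ped$mother_id),
               sex_code, 0L,
               ifelse(is.na(ped$twin_group), "0", ped$twin_group)),
    paths["ped"], sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$callset$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$labels$variants, paths["truth_variants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$labels$samples, paths["truth_samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Read a PED-format pedigree
#'
#' @param path PED file (family, individual, father, mother, sex, phenotype,
#'   optional twin-group column; "0" = missing).
#' @return A [Pedigree].
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  role <- ifelse(ped$V3 != "0" | ped$V4 != "0", "child",
                 ifelse(ped$V5 == 2, "mother", "father"))
  Pedigree(family_id = as.character(ped$V1), individual_id = as.character(ped$V2),
           father_id = ifelse(ped$V3 == "0", NA, as.character(ped$V3)),
           mother_id = ifelse(ped$V4 == "0", NA, as.character(ped$V4)),
           role = role,
           twin_group = if (ncol(ped) >= 7)
             ifelse(ped$V7 == "0", NA, as.character(ped$V7)) else NA_character_)
}

#' Screen pre-calling lane metrics
#'
#' Threshold screen on per-sample sequencing metrics measured before variant
#' calling. A sample fails if any supplied metric falls strictly below its
#' threshold (Q30 = 75 by default: Q30 of exactly 75 passes). A sample whose
#' screened metric is missing is flagged `unevaluable`, never passed
#' silently.
#'
#' @param samples data.frame with `sample_id` and metric columns.
#' @param thresholds named list of minimum values, by metric column name.
#' @return data.frame with `sample_id`, `status` in
#'   `{pass, fail, unevaluable}` and a `reason` string.
#' @export
screen_lane_metrics <- function(samples, thresholds = list(q30 = 75)) {
  n <- nrow(samples)
  status <- rep("pass", n)
  reason <- rep("", n)
  for (metric in names(thresholds)) {
    v <- samples[[metric]]
    if (is.null(v)) v <- rep(NA_real_, n)
    miss <- is.na(v)
    fail <- !miss & v < thresholds[[metric]]
    status[miss & status != "fail"] <- "unevaluable"
    reason[miss] <- paste0(reason[miss], metric, "=missing;")
    status[fail] <- "fail"
    reason[fail] <- paste0(reason[fail], metric, "<", thresholds[[metric]], ";")
  }
  data.frame(sample_id = samples$sample_id, status = status,
             reason = sub(";$", "", reason), stringsAsFactors = FALSE)
}
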