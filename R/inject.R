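#' Inject error modes into a simulated cohort
#'
#' Layers the failure modes the QC pipeline is designed to catch onto a
#' clean simulated cohort, updating the truth labels as it goes:
#'
#' * **Cell-line somatic excess** — a fraction of parents have their DNA
#'   source switched to `cell_line` and gain private (dataset-singleton)
#'   variants in random genes, mimicking mutations selected during culture.
#' * **OxoG batch artefact** — new sites that are exclusively C>A or G>T
#'   SNVs, carried only by samples in the affected sequencing batches, with
#'   depressed QD and skewed heterozygous allele balance (~0.2).
#' * **Contamination** — selected samples gain heterozygous calls at sites
#'   where a random donor carries the alternate allele, inflating
#'   heterozygosity; their free-mix score rises above the clean distribution.
#' * **Duplicates** — intentional re-sequenced copies of existing samples
#'   appended under new ids (not in the pedigree), with light missingness
#'   noise and fresh coverage metrics.
#' * **Sample swaps** — pairs of genotype columns are exchanged while the
#'   metadata stays put, exactly the signature of a wet-lab mix-up.
#'
#' With all rates zero the input is returned unchanged.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @return The modified `sim_cohort` (callset, labels and annotation updated).
#' @export
inject_error_modes <- function(sim) {
  stopifnot(inherits(sim, "sim_cohort"))
  cfg <- sim$config
  active <- cfg$oxog_rate > 0 || cfg$contamination_fraction > 0 ||
    cfg$swap_pairs > 0 || cfg$duplicate_pairs > 0 || cfg$cellline_fraction > 0
  if (!active) return(sim)
  set.seed(cfg$seed + 999331L)
  cs <- sim$callset
  lab <- sim$labels
  ann <- sim$annotation

  new_sites <- function(n, ref, alt, carriers_gt, qd, fs, sor, mq, dp_mean,
                        ab_p, label, csq_probs) {
    ## carriers_gt: n x n_samp integer matrix of genotypes at the new sites
    contig <- sample(.AUTOSOMES, n, replace = TRUE)
    pos <- sample.int(1e7L, n)  # fresh positions; collision with existing keys is negligible
    v <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                    qd = qd, fs = fs, sor = sor, mq = mq,
                    mq_rank_sum = rnorm(n, 0, 1.1),
                    read_pos_rank_sum = rnorm(n, 0, 1.2),
                    variant_type = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snv", "indel"),
                    allele_type = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snv",
                                  ifelse(nchar(alt) > nchar(ref), "ins", "del")),
                    was_split = 0L, was_mixed = 0L, has_star = 0L,
                    n_alt_alleles = 1L, stringsAsFactors = FALSE)
    ns <- ncol(carriers_gt)
    DP <- matrix(rpois(n * ns, dp_mean), n, ns)
    GQ <- matrix(pmax(pmin(round(rnorm(n * ns, cfg$gq_mean, 15)), 99L), 0L), n, ns)
    GQ <- pmin(GQ, 2L * DP)
    AD <- matrix(0L, n, ns)
    het <- carriers_gt == 1L
    AD[het] <- rbinom(sum(het), DP[het], ab_p)
    key <- paste(v$contig, v$pos, v$ref, v$alt, sep = ":")
    csq <- sample(names(csq_probs), n, replace = TRUE, prob = csq_probs)
    ptv <- csq %in% c("stop_gained", "splice_donor", "splice_acceptor", "frameshift")
    gene <- sample(unique(ann$gene), n, replace = TRUE)
    shet <- ann$s_het[match(gene, ann$gene)]
    list(variants = v, GT = carriers_gt, DP = DP, GQ = GQ, AD = AD,
         labels = data.frame(key = key, label = label, truth_set = FALSE,
                             stringsAsFactors = FALSE),
         annotation = data.frame(key = key, gene = gene, consequence = csq,
                                 loftee_hc = as.integer(ptv & runif(n) < 0.9),
                                 cadd = ifelse(ptv, runif(n, 15, 45), runif(n, 0, 20)),
                                 af_external = 0, s_het = shet, pathogenic = FALSE,
                                 stringsAsFactors = FALSE))
  }
  appended <- list()
  n_samp <- nrow(cs$samples)

  ## ---- cell-line somatic excess ----------------------------------------
  if (cfg$cellline_fraction > 0) {
    parents <- cs$samples$sample_id[cs$samples$role %in% c("mother", "father")]
    n_cl <- round(cfg$cellline_fraction * length(parents))
    if (n_cl > 0) {
      cl <- sample(parents, n_cl)
      cs$samples$dna_source[cs$samples$sample_id %in% cl] <- "cell_line"
      lab$samples$status[lab$samples$sample_id %in% cl] <- "cell_line"
      k <- rpois(n_cl, cfg$cellline_excess)
      tot <- sum(k)
      if (tot > 0) {
        gt <- matrix(0L, tot, n_samp, dimnames = list(NULL, cs$samples$sample_id))
        gt[cbind(seq_len(tot), match(rep(cl, k), cs$samples$sample_id))] <- 1L
        rb <- sample(c("C", "G", "A", "T"), tot, replace = TRUE)
        ab <- vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        appended$cellline <- new_sites(
          tot, rb, ab, gt,
          qd = pmax(rnorm(tot, 16, 4), 2.5), fs = rexp(tot, 1 / 5),
          sor = rexp(tot, 1 / 1), mq = pmin(rnorm(tot, 59, 1.5), 60),
          dp_mean = cfg$depth_mean, ab_p = 0.35, label = "real",
          csq_probs = c(synonymous = 0.3, missense = 0.45, stop_gained = 0.08,
                        frameshift = 0.07, intron = 0.10))
      }
    }
  }

  ## ---- OxoG C>A/G>T batch artefact -------------------------------------
  if (cfg$oxog_rate > 0) {
    batches <- unique(cs$samples$batch)
    n_ab <- max(1L, round(cfg$artefact_batch_fraction * length(batches)))
    aff_batches <- sample(batches, n_ab)
    affected <- cs$samples$batch %in% aff_batches & !cs$samples$is_panel
    n_art <- if (!is.null(cfg$n_artefact_sites)) cfg$n_artefact_sites else
      max(50L, ceiling(3 * cfg$oxog_rate))
    q <- min(1, cfg$oxog_rate / n_art)
    gt <- matrix(0L, n_art, n_samp, dimnames = list(NULL, cs$samples$sample_id))
    gt[, affected] <- matrix(rbinom(n_art * sum(affected), 1L, q), n_art)
    is_ca <- runif(n_art) < 0.5
    rb <- ifelse(is_ca, "C", "G")
    ab <- ifelse(is_ca, "A", "T")
    appended$artefact <- new_sites(
      n_art, rb, ab, gt,
      qd = runif(n_art, 0.5, 6), fs = rexp(n_art, 1 / 8),
      sor = rexp(n_art, 1 / 1.6), mq = pmin(rnorm(n_art, 55, 4), 60),
      dp_mean = cfg$depth_mean * 0.8, ab_p = 0.22, label = "artefact",
      csq_probs = c(synonymous = 0.35, missense = 0.40, stop_gained = 0.05,
                    intron = 0.20))
    cs$samples$batch_affected <- affected
  }

  ## ---- append new sites, keep positions sorted within contig ------------
  if (length(appended)) {
    addv <- do.call(rbind, lapply(appended, `[[`, "variants"))
    cs$variants <- rbind(cs$variants, addv)
    cs$GT <- rbind(cs$GT, do.call(rbind, lapply(appended, `[[`, "GT")))
    cs$DP <- rbind(cs$DP, do.call(rbind, lapply(appended, `[[`, "DP")))
    cs$GQ <- rbind(cs$GQ, do.call(rbind, lapply(appended, `[[`, "GQ")))
    cs$AD_alt <- rbind(cs$AD_alt, do.call(rbind, lapply(appended, `[[`, "AD")))
    lab$variants <- rbind(lab$variants, do.call(rbind, lapply(appended, `[[`, "labels")))
    ann <- rbind(ann, do.call(rbind, lapply(appended, `[[`, "annotation")))
    nt <- nrow(cs$variants) - nrow(lab$transmission$mother)
    pad <- matrix(NA_integer_, nt, ncol(lab$transmission$mother),
                  dimnames = list(NULL, colnames(lab$transmission$mother)))
    lab$transmission$mother <- rbind(lab$transmission$mother, pad)
    lab$transmission$father <- rbind(lab$transmission$father, pad)
    ord <- order(match(cs$variants$contig, c(.AUTOSOMES, "chrX")), cs$variants$pos)
    cs$variants <- cs$variants[ord, , drop = FALSE]
    for (m in c("GT", "DP", "GQ", "AD_alt")) cs[[m]] <- cs[[m]][ord, , drop = FALSE]
    key_ord <- paste(cs$variants$contig, cs$variants$pos, cs$variants$ref,
                     cs$variants$alt, sep = ":")
    lab$variants <- lab$variants[match(key_ord, lab$variants$key), , drop = FALSE]
    ann <- ann[match(key_ord, ann$key), , drop = FALSE]
    lab$transmission$mother <- lab$transmission$mother[ord, , drop = FALSE]
    lab$transmission$father <- lab$transmission$father[ord, , drop = FALSE]
    rownames(cs$variants) <- rownames(lab$variants) <- rownames(ann) <- NULL
  }
  n_var <- nrow(cs$variants)

  ## ---- contamination ----------------------------------------------------
  if (cfg$contamination_fraction > 0) {
    eligible <- which(!cs$samples$is_panel)
    n_cont <- round(cfg$contamination_fraction * length(eligible))
    if (n_cont > 0) {
      cont <- sample(eligible, n_cont)
      w <- cfg$contamination_weight
      for (j in cont) {
        donor <- sample(setdiff(seq_len(n_samp), j), 1)
        conv <- which(!is.na(cs$GT[, j]) & cs$GT[, j] == 0L &
                      !is.na(cs$GT[, donor]) & cs$GT[, donor] > 0L &
                      runif(n_var) < pmin(1, 1.8 * w))
        ## alt-read fraction reflects the contaminant dosage: w/2 when the
        ## donor is het, w when the donor is hom-alt
        cs$GT[conv, j] <- 1L
        cs$AD_alt[conv, j] <- rbinom(length(conv), cs$DP[conv, j],
                                     w * cs$GT[conv, donor] / 2)
        ## contaminant ref reads turn hom-alt calls into apparent hets
        demote <- which(!is.na(cs$GT[, j]) & cs$GT[, j] == 2L &
                        !is.na(cs$GT[, donor]) & cs$GT[, donor] < 2L &
                        runif(n_var) < w)
        cs$GT[demote, j] <- 1L
        cs$AD_alt[demote, j] <- rbinom(length(demote), cs$DP[demote, j],
                                       1 - w * (1 - cs$GT[demote, donor] / 2))
        id <- cs$samples$sample_id[j]
        cs$samples$free_mix[j] <- min(0.5, 0.05 + w * runif(1, 0.1, 0.5))
        lab$samples$status[lab$samples$sample_id == id] <- "contaminated"
      }
    }
  }

  ## ---- intentional duplicates ------------------------------------------
  if (cfg$duplicate_pairs > 0) {
    pool <- cs$samples$sample_id[!cs$samples$is_panel &
                                 lab$samples$status == "clean"]
    src <- sample(pool, min(cfg$duplicate_pairs, length(pool)))
    for (id in src) {
      j <- match(id, cs$samples$sample_id)
      nid <- paste0(id, "_D")
      drop_gt <- runif(n_var) < 0.005
      add_col <- function(m, noise = FALSE) {
        v <- m[, j]
        if (noise) v[drop_gt] <- NA_integer_
        cbind(m, v)
      }
      cs$GT <- add_col(cs$GT, noise = TRUE)
      cs$DP <- add_col(cs$DP); cs$GQ <- add_col(cs$GQ); cs$AD_alt <- add_col(cs$AD_alt)
      newmeta <- cs$samples[j, , drop = FALSE]
      newmeta$sample_id <- nid
      newmeta$bait_coverage <- pmax(rnorm(1, 85, 3), 50)
      newmeta$on_target_depth <- pmax(rnorm(1, 65, 5), 20)
      cs$samples <- rbind(cs$samples, newmeta)
      for (m in c("GT", "DP", "GQ", "AD_alt")) colnames(cs[[m]]) <- cs$samples$sample_id
      lab$samples <- rbind(lab$samples,
                           data.frame(sample_id = nid, status = "duplicate",
                                      partner = id, stringsAsFactors = FALSE))
      lab$samples$partner[lab$samples$sample_id == id] <- nid
      n_samp <- n_samp + 1L
    }
  }

  ## ---- sample swaps (columns exchanged, metadata untouched) -------------
  if (cfg$swap_pairs > 0) {
    fam_of <- function(ids) sim$pedigree$family_id[match(ids, sim$pedigree$individual_id)]
    pool <- cs$samples$sample_id[!cs$samples$is_panel &
                                 lab$samples$status == "clean"]
    pairs <- list()
    tries <- 0
    while (length(pairs) < cfg$swap_pairs && tries < 1000) {
      cand <- sample(pool, 2)
      f <- fam_of(cand)
      tries <- tries + 1
      if (!is.na(f[1]) && !is.na(f[2]) && f[1] == f[2]) next
      pairs[[length(pairs) + 1L]] <- cand
      pool <- setdiff(pool, cand)
    }
    for (pr in pairs) {
      a <- match(pr[1], cs$samples$sample_id)
      b <- match(pr[2], cs$samples$sample_id)
      for (m in c("GT", "DP", "GQ", "AD_alt")) {
        tmp <- cs[[m]][, a]
        cs[[m]][, a] <- cs[[m]][, b]
        cs[[m]][, b] <- tmp
      }
      lab$samples$status[match(pr, lab$samples$sample_id)] <- "swapped"
      lab$samples$partner[match(pr, lab$samples$sample_id)] <- rev(pr)
    }
  }

  sim$callset <- Callset(cs$samples, cs$variants, cs$GT, cs$DP, cs$GQ, cs$AD_alt)
  sim$labels <- lab
  sim$annotation <- ann
  sim
}

#' Simulate phenotypes under an S_het-burden effect
#'
#' Generates a phenotype with the stated coefficient on the burden score plus
#' small sex and ancestry covariate effects, under a linear (Gaussian noise,
#' unit SD) or logistic link. With `effect = 0` the phenotype is exchangeable
#' with respect to the burden.
#'
#' @param burden data.frame with `sample_id` and `score` (in `[0,1]`);
#'   optional covariate columns `sex` ("M"/"F" or 0/1) and `pc1`..`pc3`.
#' @param effect signed coefficient on the burden score (per 0 to 1 contrast).
#' @param link `"linear"` or `"logistic"`.
#' @param seed integer seed.
#' @param beta_sex,beta_pc covariate coefficients.
#' @param intercept linear predictor intercept (logistic default gives ~30%
#'   baseline event frequency).
#' @return Named numeric vector of phenotypes (0/1 for logistic).
#' @export
simulate_phenotypes <- function(burden, effect, link = c("linear", "logistic"),
                                seed = 1L, beta_sex = 0.2,
                                beta_pc = c(0.3, -0.2, 0.1),
                                intercept = NULL) {
  link <- match.arg(link)
  if (any(burden$score < 0 | burden$score > 1, na.rm = TRUE)) {
    stop("burden scores must lie in [0, 1]")
  }
  set.seed(seed)
  n <- nrow(burden)
  sx <- burden$sex
  sexnum <- if (is.null(sx)) rep(0, n) else if (is.character(sx) || is.factor(sx))
    as.numeric(sx == "M") else as.numeric(sx)
  eta <- effect * burden$score + beta_sex * sexnum
  for (k in 1:3) {
    pc <- burden[[paste0("pc", k)]]
    if (!is.null(pc)) eta <- eta + beta_pc[k] * pc
  }
  if (link == "linear") {
    y <- (if (is.null(intercept)) 0 else intercept) + eta + rnorm(n)
  } else {
    ic <- if (is.null(intercept)) stats::qlogis(0.3) else intercept
    y <- rbinom(n, 1L, stats::plogis(ic + eta))
  }
  stats::setNames(y, burden$sample_id)
}

#' Simulate parental singleton sites in complete trios
#'
#' Builds the trio-calibration fixture: `n_sites` synonymous sites at each of
#' which exactly one parent (chosen uniformly) is heterozygous for an allele
#' seen nowhere else among the parents, and the child of that trio inherits
#' it with probability 1/2. All other genotypes are homozygous reference.
#' Under unbiased transmission and no genotyping error the
#' transmitted/untransmitted ratio computed by [tu_ratio()] is binomially
#' distributed around 1.
#'
#' @param n_trios number of complete trios.
#' @param n_sites number of singleton sites.
#' @param seed integer seed.
#' @return List with `callset`, `pedigree`, `annotation` and the true
#'   `transmitted` logical vector per site.
#' @export
simulate_transmission_fixture <- function(n_trios, n_sites, seed = 1L) {
  set.seed(seed)
  fam <- sprintf("FAM%05d", seq_len(n_trios))
  ids <- c(rbind(paste0(fam, "_M"), paste0(fam, "_F"), paste0(fam, "_C1")))
  role <- rep(c("mother", "father", "child"), n_trios)
  ped <- Pedigree(family_id = rep(fam, each = 3), individual_id = ids,
                  father_id = ifelse(role == "child", paste0(rep(fam, each = 3), "_F"), NA),
                  mother_id = ifelse(role == "child", paste0(rep(fam, each = 3), "_M"), NA),
                  role = role)
  n_samp <- 3L * n_trios
  GT <- matrix(0L, n_sites, n_samp, dimnames = list(NULL, ids))
  trio <- sample.int(n_trios, n_sites, replace = TRUE)
  which_parent <- sample.int(2L, n_sites, replace = TRUE)  # 1 = mother, 2 = father
  parent_col <- (trio - 1L) * 3L + which_parent
  child_col <- trio * 3L
  transmitted <- rbinom(n_sites, 1L, 0.5) == 1L
  GT[cbind(seq_len(n_sites), parent_col)] <- 1L
  GT[cbind(seq_len(n_sites), child_col)] <- as.integer(transmitted)
  samples <- data.frame(sample_id = ids, role = role, stringsAsFactors = FALSE)
  variants <- data.frame(contig = "chr1", pos = seq_len(n_sites),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  cs <- Callset(samples, variants, GT)
  annotation <- data.frame(key = variant_keys(cs), gene = "G_chr1_1",
                           consequence = "synonymous", stringsAsFactors = FALSE)
  list(callset = cs, pedigree = ped, annotation = annotation,
       transmitted = transmitted)
}
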