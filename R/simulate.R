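#' Synthetic cohort configuration
#'
#' Defines the study conditions for a simulated birth cohort: trio families
#' with Mendelian transmission, optional monozygotic twins, one or more
#' ancestral populations with Balding-Nichols divergence, per-genotype
#' depth/quality emission, and the error modes the QC pipeline is built to
#' catch (an OxoG-style C>A/G>T batch artefact, cross-sample contamination,
#' sample swaps, intentional duplicates and cell-line somatic excess).
#' Error-mode rates default to zero: the base configuration is a clean
#' cohort, and each scenario switches on exactly the modes it studies.
#'
#' @param n_families number of complete trios (mother, father, child).
#' @param n_singletons number of unrelated samples without declared family.
#' @param n_panel number of labelled reference-panel samples (unrelated,
#'   marked `is_panel` in the metadata; used for ancestry assignment).
#' @param n_populations number of ancestral populations (>= 1).
#' @param twin_pairs number of families whose child has a monozygotic twin.
#' @param n_sites number of variant records before error injection.
#' @param x_fraction fraction of sites placed on chrX (males hemizygous).
#' @param indel_fraction fraction of sites that are short indels.
#' @param transition_fraction target fraction of transitions among SNVs
#'   (0.7 gives Ti/Tv ~ 2.3, typical of clean exome data).
#' @param beta_shape1,beta_shape2 Beta allele-frequency spectrum parameters.
#' @param fst Balding-Nichols divergence between populations.
#' @param missing_rate fraction of genotypes set to missing (call-rate
#'   structure of real callsets).
#' @param depth_mean mean genotype depth (DP), exome-like at 60.
#' @param gq_mean centre of the genotype-quality distribution.
#' @param lowgq_rate fraction of genotypes redrawn as low-depth/low-quality.
#' @param truth_set_rate probability that a common real site is a member of
#'   the external truth sets used to label random-forest training data.
#' @param lowqual_rate fraction of real sites drawing a hard-filter-failing
#'   annotation (genuinely poor calls, not batch artefacts).
#' @param artefact_batch_fraction fraction of sequencing batches affected by
#'   the OxoG artefact when `oxog_rate > 0`.
#' @param oxog_rate expected artefact C>A/G>T het calls per affected sample.
#' @param n_artefact_sites number of injected artefact sites (default
#'   `max(50, ceiling(3 * oxog_rate))`).
#' @param contamination_fraction fraction of samples contaminated.
#' @param contamination_weight DNA mixing weight of the contaminant.
#' @param swap_pairs number of sample-column swap pairs to inject.
#' @param duplicate_pairs number of intentional duplicate samples to append.
#' @param cellline_fraction fraction of parents whose DNA source becomes an
#'   immortalised cell line.
#' @param cellline_excess expected extra private (somatic-like) variants per
#'   cell-line sample.
#' @param batch_size samples per sequencing batch.
#' @param seed integer seed; a fixed seed fixes every emitted byte.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 150, n_singletons = 50, n_panel = 0,
                       n_populations = 2, twin_pairs = 0,
                       n_sites = 4000, x_fraction = 0.05, indel_fraction = 0.1,
                       transition_fraction = 0.7,
                       beta_shape1 = 0.6, beta_shape2 = 6, fst = 0.1,
                       missing_rate = 0.002,
                       depth_mean = 60, gq_mean = 80, lowgq_rate = 0.03,
                       truth_set_rate = 0.6, lowqual_rate = 0.02,
                       artefact_batch_fraction = 0.25, oxog_rate = 0,
                       n_artefact_sites = NULL,
                       contamination_fraction = 0, contamination_weight = 0.5,
                       swap_pairs = 0, duplicate_pairs = 0,
                       cellline_fraction = 0, cellline_excess = 5,
                       batch_size = 96, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c("x_fraction", "indel_fraction", "transition_fraction",
             "artefact_batch_fraction", "contamination_fraction",
             "contamination_weight", "cellline_fraction", "truth_set_rate",
             "lowqual_rate", "lowgq_rate", "missing_rate")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("invalid configuration: '", p, "' must be a probability in [0, 1]")
    }
  }
  counts <- c("n_families", "n_singletons", "n_panel", "n_populations",
              "twin_pairs", "n_sites", "swap_pairs", "duplicate_pairs",
              "batch_size")
  for (p in counts) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      stop("invalid configuration: '", p, "' must be a non-negative count")
    }
    cfg[[p]] <- as.integer(v)
  }
  if (cfg$n_populations < 1L) stop("invalid configuration: 'n_populations' must be >= 1")
  for (p in c("depth_mean", "gq_mean", "oxog_rate", "cellline_excess",
              "beta_shape1", "beta_shape2")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop("invalid configuration: '", p, "' must be non-negative")
    }
  }
  if (cfg$depth_mean <= 0) stop("invalid configuration: 'depth_mean' must be positive")
  if (cfg$gq_mean <= 0) stop("invalid configuration: 'gq_mean' must be positive")
  if (!is.numeric(cfg$fst) || cfg$fst < 0 || cfg$fst >= 1) {
    stop("invalid configuration: 'fst' must be in [0, 1)")
  }
  if (!is.null(cfg$n_artefact_sites)) {
    if (cfg$n_artefact_sites < 0) stop("invalid configuration: 'n_artefact_sites' must be non-negative")
    cfg$n_artefact_sites <- as.integer(cfg$n_artefact_sites)
  }
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$twin_pairs > cfg$n_families) stop("invalid configuration: 'twin_pairs' exceeds n_families")
  class(cfg) <- "sim_config"
  cfg
}

.TI <- c(A = "G", G = "A", C = "T", T = "C")
.TV <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
.AUTOSOMES <- paste0("chr", 1:22)

#' Simulate a clean labelled cohort
#'
#' Draws allele frequencies from a Beta spectrum with Balding-Nichols
#' population divergence, genotypes for founders and Mendelian transmission
#' for children, per-genotype DP/GQ/allelic depths, GATK-style site
#' annotations with separate distributions for genuinely poor calls, a
#' truth-set membership flag, and a variant annotation table (gene,
#' consequence, LOFTEE-style confidence, CADD-style score, external allele
#' frequency, s_het). Everything is labelled: the returned `labels` element
#' carries per-variant {real, artefact} and truth-set flags, per-sample
#' status, and the transmitted allele of each parent for every child.
#'
#' No error modes are injected here: use [inject_error_modes()] for the
#' artefact/contamination/swap/duplicate/cell-line layers.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `callset` ([Callset]),
#'   `pedigree` ([Pedigree]), `labels`, `annotation` (data.frame) and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  ## ---- pedigree and sample metadata -------------------------------------
  ped_rows <- list(); meta_rows <- list()
  add_sample <- function(id, pop, sex, role) {
    meta_rows[[length(meta_rows) + 1L]] <<- data.frame(
      sample_id = id, population = pop, sex = sex, role = role,
      stringsAsFactors = FALSE)
  }
  pops <- paste0("pop", seq_len(config$n_populations))
  for (i in seq_len(config$n_families)) {
    fam <- sprintf("FAM%04d", i)
    pop <- pops[(i - 1L) %% length(pops) + 1L]
    m <- paste0(fam, "_M"); f <- paste0(fam, "_F"); c1 <- paste0(fam, "_C1")
    twin <- i <= config$twin_pairs
    add_sample(m, pop, "F", "mother"); add_sample(f, pop, "M", "father")
    csex <- sample(c("M", "F"), 1)
    add_sample(c1, pop, csex, "child")
    ped_rows[[length(ped_rows) + 1L]] <- data.frame(
      family_id = fam, individual_id = c(m, f, c1),
      father_id = c(NA, NA, f), mother_id = c(NA, NA, m),
      role = c("mother", "father", "child"),
      twin_group = c(NA, NA, if (twin) fam else NA), stringsAsFactors = FALSE)
    if (twin) {
      c2 <- paste0(fam, "_C2")
      add_sample(c2, pop, csex, "child")
      ped_rows[[length(ped_rows) + 1L]] <- data.frame(
        family_id = fam, individual_id = c2, father_id = f, mother_id = m,
        role = "child", twin_group = fam, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(config$n_singletons)) {
    add_sample(sprintf("S%04d", i), pops[(i - 1L) %% length(pops) + 1L],
               sample(c("M", "F"), 1), "singleton")
  }
  for (i in seq_len(config$n_panel)) {
    add_sample(sprintf("P%04d", i), pops[(i - 1L) %% length(pops) + 1L],
               sample(c("M", "F"), 1), "panel")
  }
  meta <- do.call(rbind, meta_rows)
  n_samp <- nrow(meta)
  pedigree <- if (length(ped_rows)) {
    pr <- do.call(rbind, ped_rows)
    Pedigree(pr$family_id, pr$individual_id, pr$father_id, pr$mother_id,
             pr$role, pr$twin_group)
  } else {
    Pedigree(character(), character(), character(), character(), character(),
             character())
  }
  meta$cohort <- "SYN"
  meta$batch <- sprintf("B%02d", (seq_len(n_samp) - 1L) %/% config$batch_size + 1L)
  meta$dna_source <- "blood"
  meta$reported_sex <- meta$sex
  meta$free_mix <- runif(n_samp, 0, 0.03)
  meta$q30 <- runif(n_samp, 85, 96)
  meta$yield_gb <- pmax(rnorm(n_samp, 7, 1), 1)
  meta$gc_fraction <- rnorm(n_samp, 0.5, 0.02)
  meta$pulldown_pct <- pmin(pmax(rnorm(n_samp, 70, 5), 30), 95)
  meta$on_target_depth <- pmax(rnorm(n_samp, 65, 5), 20)
  meta$bait_coverage <- pmax(rnorm(n_samp, 85, 3), 50)
  meta$y_depth <- ifelse(meta$sex == "M",
                         pmax(rnorm(n_samp, 1, 0.08), 0.5),
                         pmax(rnorm(n_samp, 0.02, 0.01), 0))
  meta$is_panel <- meta$role == "panel"

  ## ---- sites ------------------------------------------------------------
  n_x <- round(config$n_sites * config$x_fraction)
  n_auto <- config$n_sites - n_x
  contig <- c(rep(.AUTOSOMES, length.out = n_auto),
              rep("chrX", n_x))
  variants <- data.frame(contig = contig, pos = 0L, stringsAsFactors = FALSE)
  for (ctg in unique(contig)) {
    idx <- which(contig == ctg)
    variants$pos[idx] <- sort(sample.int(1e7L, length(idx)))
  }
  ord <- order(match(variants$contig, c(.AUTOSOMES, "chrX")), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  n_var <- nrow(variants)
  is_indel <- runif(n_var) < config$indel_fraction
  ref_base <- sample(c("A", "C", "G", "T"), n_var, replace = TRUE)
  alt <- character(n_var)
  is_ti <- runif(n_var) < config$transition_fraction
  alt[!is_indel & is_ti] <- .TI[ref_base[!is_indel & is_ti]]
  tv_idx <- which(!is_indel & !is_ti)
  alt[tv_idx] <- vapply(ref_base[tv_idx], function(b) sample(.TV[[b]], 1), "")
  variants$ref <- ref_base
  variants$alt <- alt
  if (any(is_indel)) {
    for (i in which(is_indel)) {
      extra <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
                     collapse = "")
      if (runif(1) < 0.5) {            # insertion
        variants$alt[i] <- paste0(ref_base[i], extra)
      } else {                          # deletion
        variants$ref[i] <- paste0(ref_base[i], extra)
        variants$alt[i] <- ref_base[i]
      }
    }
  }

  ## ---- allele frequencies (Balding-Nichols) -----------------------------
  p_anc <- pmin(pmax(rbeta(n_var, config$beta_shape1, config$beta_shape2), 5e-4), 0.5)
  P <- matrix(p_anc, n_var, config$n_populations)
  if (config$fst > 0 && config$n_populations > 1) {
    f <- config$fst
    for (k in seq_len(config$n_populations)) {
      P[, k] <- rbeta(n_var, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
    P <- pmin(pmax(P, 1e-4), 0.999)
  }

  ## ---- genotypes --------------------------------------------------------
  on_x <- variants$contig == "chrX"
  GT <- matrix(NA_integer_, n_var, n_samp, dimnames = list(NULL, meta$sample_id))
  pop_idx <- match(meta$population, pops)
  founder <- meta$role != "child"
  for (j in which(founder)) {
    p <- P[, pop_idx[j]]
    g <- rbinom(n_var, 2L, p)
    if (meta$sex[j] == "M") g[on_x] <- 2L * rbinom(sum(on_x), 1L, p[on_x])
    GT[, j] <- g
  }
  child_ids <- meta$sample_id[meta$role == "child"]
  mat_trans <- matrix(NA_integer_, n_var, length(child_ids),
                      dimnames = list(NULL, child_ids))
  pat_trans <- mat_trans
  done_twin <- character()
  for (cid in child_ids) {
    prow <- pedigree[pedigree$individual_id == cid, ]
    tw <- prow$twin_group
    sib <- if (!is.na(tw)) intersect(done_twin,
      pedigree$individual_id[!is.na(pedigree$twin_group) & pedigree$twin_group == tw])
      else character()
    if (length(sib)) {                 # monozygotic twin: identical genome
      GT[, cid] <- GT[, sib[1]]
      mat_trans[, cid] <- mat_trans[, sib[1]]
      pat_trans[, cid] <- pat_trans[, sib[1]]
    } else {
      gm <- GT[, prow$mother_id]; gf <- GT[, prow$father_id]
      am <- rbinom(n_var, 1L, gm / 2)
      af <- rbinom(n_var, 1L, gf / 2)
      g <- am + af
      if (meta$sex[meta$sample_id == cid] == "M") {
        g[on_x] <- 2L * am[on_x]
        af[on_x] <- NA_integer_
      } else {
        g[on_x] <- am[on_x] + gf[on_x] / 2L   # father hemizygous: passes his allele
        af[on_x] <- gf[on_x] / 2L
      }
      GT[, cid] <- as.integer(g)
      mat_trans[, cid] <- am
      pat_trans[, cid] <- as.integer(af)
    }
    if (!is.na(tw)) done_twin <- c(done_twin, cid)
  }

  ## ---- depth, quality, allelic depth ------------------------------------
  nm <- n_var * n_samp
  DP <- matrix(rpois(nm, config$depth_mean), n_var, n_samp)
  low <- matrix(runif(nm) < config$lowgq_rate, n_var, n_samp)
  DP[low] <- rpois(sum(low), 8)
  GQ <- matrix(pmax(pmin(round(rnorm(nm, config$gq_mean, 12)), 99L), 0L), n_var, n_samp)
  GQ <- pmin(GQ, 2L * DP)
  AD <- matrix(0L, n_var, n_samp)
  het <- !is.na(GT) & GT == 1L
  homa <- !is.na(GT) & GT == 2L
  homr <- !is.na(GT) & GT == 0L
  AD[het] <- rbinom(sum(het), DP[het], 0.5)
  AD[homa] <- DP[homa] - rbinom(sum(homa), DP[homa], 0.005)
  AD[homr] <- rbinom(sum(homr), DP[homr], 0.005)
  if (config$missing_rate > 0) GT[runif(nm) < config$missing_rate] <- NA_integer_
  dimnames(DP) <- dimnames(GQ) <- dimnames(AD) <- dimnames(GT)

  ## ---- site annotations --------------------------------------------------
  qd <- pmax(rnorm(n_var, 20, 5), 0.5)
  fs <- rexp(n_var, 1 / 4)
  mq <- pmin(rnorm(n_var, 59.5, 1.2), 60)
  lowq <- which(runif(n_var) < config$lowqual_rate)
  if (length(lowq)) {
    which_fail <- sample(1:3, length(lowq), replace = TRUE)
    qd[lowq[which_fail == 1]] <- runif(sum(which_fail == 1), 0.3, 1.9)
    fs[lowq[which_fail == 2]] <- runif(sum(which_fail == 2), 61, 120)
    mq[lowq[which_fail == 3]] <- runif(sum(which_fail == 3), 10, 29)
  }
  variants$qd <- qd
  variants$fs <- fs
  variants$sor <- rexp(n_var, 1 / 0.9)
  variants$mq <- mq
  variants$mq_rank_sum <- rnorm(n_var, 0, 0.6)
  variants$read_pos_rank_sum <- rnorm(n_var, 0, 0.8)
  no_het <- rowSums(het) == 0L
  variants$mq_rank_sum[no_het] <- NA_real_      # no het carriers: rank sums absent
  variants$read_pos_rank_sum[no_het] <- NA_real_
  variants$variant_type <- ifelse(nchar(variants$ref) == 1 & nchar(variants$alt) == 1,
                                  "snv", "indel")
  variants$allele_type <- ifelse(variants$variant_type == "snv", "snv",
                          ifelse(nchar(variants$alt) > nchar(variants$ref), "ins", "del"))
  variants$was_split <- as.integer(runif(n_var) < 0.05)
  variants$was_mixed <- as.integer(variants$was_split == 1L & runif(n_var) < 0.2)
  variants$has_star <- as.integer(runif(n_var) < 0.01)
  variants$n_alt_alleles <- ifelse(variants$was_split == 1L,
                                   2L + rpois(n_var, 0.3), 1L)

  callset <- Callset(meta, variants, GT, DP = DP, GQ = GQ, AD_alt = AD)
  key <- variant_keys(callset)

  ## ---- annotation table --------------------------------------------------
  gene <- paste0("G_", variants$contig, "_",
                 ave(variants$pos, variants$contig,
                     FUN = function(p) ceiling(rank(p) / 10)))
  genes <- unique(gene)
  s_het_map <- stats::setNames(pmin(rbeta(length(genes), 0.4, 4), 0.95), genes)
  csq <- character(n_var)
  snv_i <- variants$variant_type == "snv"
  csq[snv_i] <- sample(c("synonymous", "missense", "stop_gained", "splice_donor",
                         "splice_acceptor", "frameshift", "intron"),
                       sum(snv_i), replace = TRUE,
                       prob = c(0.35, 0.40, 0.05, 0.02, 0.02, 0.00, 0.16))
  csq[!snv_i] <- sample(c("frameshift", "inframe_indel", "intron"),
                        sum(!snv_i), replace = TRUE, prob = c(0.5, 0.2, 0.3))
  ptv <- csq %in% c("stop_gained", "splice_donor", "splice_acceptor", "frameshift")
  cadd <- runif(n_var, 0, 15)
  cadd[csq == "missense"] <- runif(sum(csq == "missense"), 10, 35)
  cadd[ptv] <- runif(sum(ptv), 15, 45)
  af_ext <- p_anc * exp(rnorm(n_var, 0, 0.3))    # p_anc is in final site order
  af_ext[runif(n_var) < 0.1] <- 0                # novel relative to reference
  annotation <- data.frame(
    key = key, gene = gene, consequence = csq,
    loftee_hc = as.integer(ptv & runif(n_var) < 0.9),
    cadd = cadd, af_external = pmin(af_ext, 1),
    s_het = unname(s_het_map[gene]),
    pathogenic = FALSE, stringsAsFactors = FALSE)

  labels <- list(
    variants = data.frame(key = key, label = "real",
                          truth_set = runif(n_var) < config$truth_set_rate &
                                      p_anc > 0.001,
                          stringsAsFactors = FALSE),
    samples = data.frame(sample_id = meta$sample_id, status = "clean",
                         partner = NA_character_, stringsAsFactors = FALSE),
    transmission = list(mother = mat_trans, father = pat_trans))

  structure(list(callset = callset, pedigree = pedigree, labels = labels,
                 annotation = annotation, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$callset$variants), "variants x",
      nrow(x$callset$samples), "samples;",
      sum(x$labels$variants$label == "artefact"), "artefact sites;",
      sum(x$labels$samples$status != "clean"), "non-clean samples\n")
  invisible(x)
}
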