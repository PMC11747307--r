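#' Classify variant rarity
#'
#' Rare: internal allele frequency < 0.1% **and** external (reference
#' database) allele frequency < 0.1% — plus, in multi-ancestry mode, a
#' maximum per-population allele frequency < 0.1%. Ultra-rare additionally
#' requires external frequency < 0.003% (roughly "absent from a combined
#' ~200k reference set at more than a handful of copies"). All inequalities
#' strict. Variants without an external frequency are treated as absent
#' from the reference (frequency 0) with a provenance flag.
#'
#' @param internal_af internal allele frequency (computed on unrelated
#'   probands).
#' @param external_af external reference allele frequency (`NA` = absent).
#' @param pop_max_af optional maximum allele frequency across the cohort's
#'   major ancestry groups.
#' @param multi_ancestry apply the `pop_max_af` filter.
#' @param rare_af,ultra_rare_af thresholds (0.001 and 0.00003).
#' @return data.frame with `rarity` in `{common, rare, ultra_rare}` and
#'   `external_missing` flag.
#' @export
classify_rarity <- function(internal_af, external_af, pop_max_af = NULL,
                            multi_ancestry = FALSE, rare_af = 0.001,
                            ultra_rare_af = 0.00003) {
  stopifnot(all(internal_af >= 0 & internal_af <= 1, na.rm = TRUE))
  ext_missing <- is.na(external_af)
  ext <- ifelse(ext_missing, 0, external_af)
  rare <- internal_af < rare_af & ext < rare_af
  if (multi_ancestry) {
    if (is.null(pop_max_af)) stop("multi_ancestry mode needs pop_max_af")
    rare <- rare & pop_max_af < rare_af
  }
  ultra <- rare & ext < ultra_rare_af
  data.frame(rarity = ifelse(ultra, "ultra_rare", ifelse(rare, "rare", "common")),
             external_missing = ext_missing, stringsAsFactors = FALSE)
}

#' High-confidence protein-truncating variant call
#'
#' TRUE iff the consequence is splice-donor, splice-acceptor or frameshift,
#' or stop-gained with CADD-style deleteriousness score strictly above 25 —
#' and the LOFTEE-style high-confidence flag is set. A missing
#' high-confidence flag is conservative FALSE.
#'
#' @param consequence consequence string per variant.
#' @param cadd deleteriousness score.
#' @param loftee_hc high-confidence flag (1/0 or logical).
#' @param cadd_min CADD bound for stop-gained (default 25, strict).
#' @return Logical vector.
#' @export
is_hc_ptv <- function(consequence, cadd, loftee_hc, cadd_min = 25) {
  hc <- !is.na(loftee_hc) & as.logical(loftee_hc)
  base <- consequence %in% c("splice_donor", "splice_acceptor", "frameshift") |
          (consequence == "stop_gained" & !is.na(cadd) & cadd > cadd_min)
  base & hc
}

#' Per-gene-aggregated S_het burden score
#'
#' `1 - prod_g (1 - s_het[g])` over the **distinct** genes carrying at
#' least one qualifying variant; multiple qualifying variants in one gene
#' count once. Scores lie in `[0, 1)`, are order-invariant over genes and
#' strictly increasing in any gene's s_het.
#'
#' @param genes character vector of qualifying genes for one sample
#'   (duplicates allowed).
#' @param s_het_map named numeric vector of per-gene selection coefficients
#'   in `[0, 1)`.
#' @return Single burden score.
#' @export
shet_burden <- function(genes, s_het_map) {
  g <- unique(genes)
  known <- g %in% names(s_het_map)
  if (any(!known)) {
    warning("skipping gene(s) without s_het: ", paste(g[!known], collapse = ", "))
    g <- g[known]
  }
  if (!length(g)) return(0)
  s <- s_het_map[g]
  if (any(s < 0 | s >= 1)) stop("s_het values must lie in [0, 1)")
  1 - prod(1 - s)
}

#' Per-sample burden table for a variant class
#'
#' Finds each sample's qualifying variants (ultra-rare by default, in the
#' requested consequence class), the distinct genes hit, and the aggregated
#' S_het burden score.
#'
#' @param callset A [Callset].
#' @param annotation data.frame with `key`, `gene`, `consequence`, `cadd`,
#'   `loftee_hc`, `s_het`.
#' @param rarity data.frame from [classify_rarity()] aligned to the callset
#'   variants.
#' @param class `"hc_ptv"` or a consequence string such as `"synonymous"`.
#' @param rarity_level qualifying rarity (default `"ultra_rare"`).
#' @return data.frame with `sample_id`, `n_variants`, `n_genes`, `score`.
#' @export
burden_table <- function(callset, annotation, rarity, class = "hc_ptv",
                         rarity_level = "ultra_rare") {
  keys <- variant_keys(callset)
  ann <- annotation[match(keys, annotation$key), , drop = FALSE]
  in_class <- if (class == "hc_ptv") {
    is_hc_ptv(ann$consequence, ann$cadd, ann$loftee_hc)
  } else {
    !is.na(ann$consequence) & ann$consequence == class
  }
  qual <- in_class & rarity$rarity == rarity_level
  s_het_map <- tapply(annotation$s_het, annotation$gene, function(x) x[1])
  gt <- callset$GT[qual, , drop = FALSE]
  genes_q <- ann$gene[qual]
  out <- data.frame(sample_id = callset$samples$sample_id,
                    n_variants = 0L, n_genes = 0L, score = 0,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(gt))) {
    carried <- !is.na(gt[, j]) & gt[, j] > 0L
    out$n_variants[j] <- sum(carried)
    gset <- genes_q[carried]
    out$n_genes[j] <- length(unique(gset))
    out$score[j] <- if (length(gset)) shet_burden(gset, s_het_map) else 0
  }
  out
}

#' Blom rank-normal transform
#'
#' `z = qnorm((rank - 3/8) / (n + 1/4))` with average ranks for ties.
#' Invariant under monotone transforms of the input.
#'
#' @param values numeric vector with at least two distinct values.
#' @return Numeric z-scores.
#' @export
rank_normalise <- function(values) {
  ok <- !is.na(values)
  if (length(unique(values[ok])) < 2) stop("rank normalisation needs >= 2 distinct values")
  r <- rank(values[ok], ties.method = "average")
  z <- rep(NA_real_, length(values))
  z[ok] <- stats::qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  z
}

#' Test the association of a burden score with a phenotype
#'
#' Regression of the phenotype on the S_het burden score with sex and three
#' principal components as covariates; the coefficient is interpreted per
#' unit of burden (the 0 to 1 contrast). Logistic separation is detected
#' and flagged rather than silently returned.
#'
#' @param burden data.frame with `sample_id` and `score`.
#' @param phenotype named numeric vector (binary for logistic).
#' @param covariates data.frame with `sample_id` and covariate columns
#'   (e.g. `sex`, `pc1`..`pc3`); optional.
#' @param family `"linear"` or `"logistic"`.
#' @return List with `coefficient`, `se`, `p`, `n`, `separation` flag and
#'   the fitted model.
#' @export
associate_burden <- function(burden, phenotype, covariates = NULL,
                             family = c("linear", "logistic")) {
  family <- match.arg(family)
  dat <- data.frame(sample_id = burden$sample_id, score = burden$score,
                    stringsAsFactors = FALSE)
  dat$y <- phenotype[match(dat$sample_id, names(phenotype))]
  if (!is.null(covariates)) {
    dat <- merge(dat, covariates, by = "sample_id")
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (family == "logistic" && !all(dat$y %in% c(0, 1))) {
    stop("logistic family needs a binary phenotype")
  }
  rhs <- setdiff(names(dat), c("sample_id", "y"))
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- if (family == "linear") stats::glm(fml, data = dat) else
    stats::glm(fml, data = dat, family = stats::binomial())
  sm <- summary(fit)$coefficients
  separation <- FALSE
  if (family == "logistic") {
    mu <- stats::fitted(fit)
    separation <- any(abs(sm["score", 1]) > 15) ||
      all(mu < 1e-8 | mu > 1 - 1e-8)
  }
  list(coefficient = sm["score", 1], se = sm["score", 2],
       p = sm["score", 4], n = nrow(dat), separation = separation,
       fit = fit)
}

#' Per-gene carrier-count comparison between DNA sources
#'
#' Two-sided Fisher's exact test per gene-filter combination on the 2x2
#' table of carriers versus non-carriers by DNA source, with a Bonferroni
#' threshold accounting for 18 tests (2 consequence classes x 3 QC
#' stringencies x 3 missingness filters) per gene.
#'
#' @param counts data.frame with `gene`, `filter_combo`, `carriers_blood`,
#'   `n_blood`, `carriers_cell`, `n_cell`.
#' @param n_filter_tests tests per gene for the Bonferroni family
#'   (default 18).
#' @param alpha family-wise level.
#' @return The input with `p`, `threshold` and `significant` columns,
#'   sorted by p.
#' @export
dna_source_gene_tests <- function(counts, n_filter_tests = 18, alpha = 0.05) {
  stopifnot(all(counts$carriers_blood >= 0, counts$carriers_cell >= 0))
  n_genes <- length(unique(counts$gene))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    tab <- matrix(c(counts$carriers_blood[i],
                    counts$n_blood[i] - counts$carriers_blood[i],
                    counts$carriers_cell[i],
                    counts$n_cell[i] - counts$carriers_cell[i]), 2)
    if (any(tab < 0)) stop("carrier count exceeds sample count in row ", i)
    ## zero-margin tables carry no information
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
        sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) return(1)
    stats::fisher.test(tab)$p.value
  }, 0)
  out <- counts
  out$p <- p
  out$threshold <- alpha / (n_filter_tests * n_genes)
  out$significant <- out$p < out$threshold
  out[order(out$p), , drop = FALSE]
}

#' Estimate the per-sample variant-count excess of cell-line DNA
#'
#' Linear regression of per-sample variant counts on DNA source plus three
#' principal components; the DNA-source coefficient estimates how many
#' extra variants cell-line samples harbour on average.
#'
#' @param counts data.frame with `sample_id`, `count`, `dna_source`
#'   (`blood`/`cell_line`) and optional `pc1`..`pc3`.
#' @return List with `excess` (coefficient), `se`, `p`, `n`.
#' @export
dna_source_count_regression <- function(counts) {
  stopifnot(all(counts$count >= 0), all(counts$count == round(counts$count)))
  if (length(unique(counts$dna_source)) < 2) {
    stop("both DNA sources must be present")
  }
  counts$src <- as.integer(counts$dna_source == "cell_line")
  rhs <- c("src", intersect(c("pc1", "pc2", "pc3"), names(counts)))
  fml <- stats::as.formula(paste("count ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = counts)
  sm <- summary(fit)$coefficients
  list(excess = sm["src", 1], se = sm["src", 2], p = sm["src", 4],
       n = nrow(counts), fit = fit)
}

#' Exact Poisson test of a genetic prevalence
#'
#' Compares the observed number of children with a disease-compatible
#' genotype to the count expected from the population incidence. The
#' expected count is `round(N * incidence)`; the two-sided exact Poisson
#' test sums the probabilities of all outcomes no more likely than the
#' observed one, against the rounded expectation by default (the unrounded
#' mean is available via `round_mean = FALSE`). The 95% CI is the exact
#' (Garwood, chi-square) interval for a count equal to the rounded
#' expectation, endpoints rounded to the nearest integer.
#'
#' @param n_children number of (maximally unrelated) children.
#' @param observed observed count of affected genotypes.
#' @param incidence population incidence in (0, 1).
#' @param conf_level CI level.
#' @param round_mean test against the rounded expected count.
#' @return List of class `prevalence_result`: `n_children`, `incidence`,
#'   `expected`, `observed`, `p`, `ci_lower`, `ci_upper`.
#' @export
prevalence_test <- function(n_children, observed, incidence,
                            conf_level = 0.95, round_mean = TRUE) {
  if (n_children <= 0) stop("no children to evaluate")
  if (incidence <= 0 || incidence >= 1) stop("incidence must be in (0, 1)")
  mu <- n_children * incidence
  expected <- round(mu)
  p <- stats::poisson.test(observed, r = if (round_mean) expected else mu,
                           alternative = "two.sided")$p.value
  a <- 1 - conf_level
  ci <- c(stats::qchisq(a / 2, 2 * expected) / 2,
          stats::qchisq(1 - a / 2, 2 * expected + 2) / 2)
  structure(list(n_children = n_children, incidence = incidence,
                 expected = expected, observed = observed, p = p,
                 ci_lower = round(ci[1]), ci_upper = round(ci[2])),
            class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, ...) {
  cat(sprintf(paste0("Genetic prevalence: %d observed vs %d expected among ",
                     "%d children\n  (incidence %.5g; 95%% CI %d-%d; ",
                     "two-sided exact Poisson p = %.4g)\n"),
              x$observed, x$expected, x$n_children, x$incidence,
              x$ci_lower, x$ci_upper, x$p))
  invisible(x)
}

#' Genetic prevalence of a recessive disorder from a callset
#'
#' Counts children homozygous for any flagged pathogenic variant in the
#' gene (compound heterozygotes deliberately not considered) among a
#' maximally unrelated child set, and runs [prevalence_test()].
#'
#' @param callset A [Callset].
#' @param annotation annotation table with `key`, `gene` and logical
#'   `pathogenic`.
#' @param gene gene symbol.
#' @param incidence population incidence of the disorder.
#' @param children child sample ids to consider.
#' @param kinship optional kinship table for unrelated selection via
#'   [select_unrelated()].
#' @param ... passed to [prevalence_test()].
#' @return A `prevalence_result`.
#' @export
genetic_prevalence <- function(callset, annotation, gene, incidence,
                               children, kinship = NULL, ...) {
  if (!length(children)) stop("no children to evaluate")
  if (!is.null(kinship)) children <- select_unrelated(children, kinship)
  keys <- variant_keys(callset)
  ann <- annotation[match(keys, annotation$key), , drop = FALSE]
  patho <- which(!is.na(ann$pathogenic) & ann$pathogenic & ann$gene == gene)
  gt <- callset$GT[patho, children, drop = FALSE]
  observed <- sum(apply(gt, 2, function(g) any(!is.na(g) & g == 2L)))
  prevalence_test(length(children), observed, incidence, ...)
}
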