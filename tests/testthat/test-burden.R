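test_that("rarity classification applies strict thresholds", {
  r <- classify_rarity(internal_af = c(0.0005, 0.001, 0.0005, 0.0004),
                       external_af = c(0.00001, 0.0005, 0.002, NA))
  expect_equal(r$rarity, c("ultra_rare", "common", "common", "ultra_rare"))
  expect_true(r$external_missing[4])        # absent-from-reference convention
  ## multi-ancestry population-maximum filter
  r2 <- classify_rarity(0.0004, 0.0004, pop_max_af = 0.002,
                        multi_ancestry = TRUE)
  expect_equal(r2$rarity, "common")
  expect_error(classify_rarity(0.0004, 0.0004, multi_ancestry = TRUE),
               "pop_max_af")
  ## monotone: lowering any frequency never makes a variant more common
  set.seed(7)
  for (i in 1:50) {
    iaf <- runif(1, 0, 0.01); eaf <- runif(1, 0, 0.01)
    lv <- function(x) c(common = 0, rare = 1, ultra_rare = 2)[x]
    a <- lv(classify_rarity(iaf, eaf)$rarity)
    b <- lv(classify_rarity(iaf / 2, eaf)$rarity)
    d <- lv(classify_rarity(iaf, eaf / 2)$rarity)
    expect_gte(b, a); expect_gte(d, a)
  }
})

test_that("high-confidence PTV rules follow consequence, CADD and confidence", {
  expect_true(is_hc_ptv("stop_gained", 26, 1))
  expect_false(is_hc_ptv("stop_gained", 25, 1))       # strict > 25
  expect_true(is_hc_ptv("splice_donor", 2, 1))        # CADD only gates stops
  expect_true(is_hc_ptv("frameshift", NA, 1))
  expect_false(is_hc_ptv("frameshift", 40, 0))        # low-confidence fails
  expect_false(is_hc_ptv("frameshift", 40, NA))       # missing flag: FALSE
  expect_false(is_hc_ptv("missense", 40, 1))
})

test_that("S_het burden follows the complement-product formula", {
  shm <- c(A = 0.5, B = 0.2, C = 0.9)
  expect_equal(shet_burden(character(), shm), 0)
  expect_equal(shet_burden("A", shm), 0.5)
  expect_equal(shet_burden(c("A", "B"), shm), 1 - 0.5 * 0.8)
  ## repeated qualifying variants in one gene count once
  expect_equal(shet_burden(c("A", "A", "B"), shm), 0.6)
  ## order-invariant and increasing in any gene's s_het
  expect_equal(shet_burden(c("B", "A"), shm), shet_burden(c("A", "B"), shm))
  shm2 <- shm; shm2["B"] <- 0.3
  expect_gt(shet_burden(c("A", "B"), shm2), shet_burden(c("A", "B"), shm))
  expect_warning(s <- shet_burden(c("A", "ZZZ"), shm), "ZZZ")
  expect_equal(s, 0.5)
  expect_error(shet_burden("A", c(A = 1)), "\\[0, 1\\)")
})

test_that("burden table aggregates qualifying ultra-rare variants per gene", {
  gt <- matrix(c(1L, 1L, 0L,
                 0L, 1L, 0L,
                 1L, 0L, 0L,
                 0L, 0L, 1L), 4, 3, byrow = TRUE)
  cs <- toy_callset(gt)
  ann <- data.frame(key = variant_keys(cs),
                    gene = c("A", "A", "B", "C"),
                    consequence = c("frameshift", "stop_gained", "frameshift",
                                    "synonymous"),
                    cadd = c(30, 30, 30, 1), loftee_hc = c(1, 1, 1, 0),
                    s_het = c(0.5, 0.5, 0.2, 0.1))
  rar <- data.frame(rarity = c("ultra_rare", "ultra_rare", "ultra_rare", "rare"))
  bt <- burden_table(cs, ann, rar, class = "hc_ptv")
  ## sample 1: genes A and B -> 1 - 0.5*0.8; sample 2: gene A twice -> 0.5
  expect_equal(bt$score, c(0.6, 0.5, 0))
  expect_equal(bt$n_genes, c(2L, 1L, 0L))
  ## rare (not ultra-rare) synonymous site does not qualify by default
  bt_syn <- burden_table(cs, ann, rar, class = "synonymous")
  expect_equal(bt_syn$score[3], 0)
})

test_that("rank normalisation matches the Blom closed form", {
  x <- c(3.2, -1, 7, 0.5, 2)
  z <- rank_normalise(x)
  r <- rank(x)
  expect_equal(z, qnorm((r - 3 / 8) / (5 + 1 / 4)))
  ## symmetric input maps to symmetric scores around zero
  expect_equal(rank_normalise(c(1, 2, 3))[2], 0)
  expect_equal(rank_normalise(c(1, 2, 3))[1], -rank_normalise(c(1, 2, 3))[3])
  ## invariant under monotone transforms
  expect_equal(rank_normalise(exp(x)), z)
  expect_error(rank_normalise(rep(1, 5)), "distinct")
})

test_that("burden association recovers signals and flags separation", {
  set.seed(31)
  n <- 3000
  bt <- data.frame(sample_id = paste0("S", 1:n),
                   score = stats::rbeta(n, 0.3, 3),
                   sex = sample(c("M", "F"), n, TRUE),
                   pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n))
  cov <- bt[, c("sample_id", "sex", "pc1", "pc2", "pc3")]
  ph <- simulate_phenotypes(bt, effect = -1, link = "linear", seed = 41)
  a <- associate_burden(bt, ph, cov, family = "linear")
  expect_lt(abs(a$coefficient - (-1)), 3 * a$se)
  ## synonymous-style negative control: independent burden, no signal
  bt_syn <- bt; set.seed(42); bt_syn$score <- stats::rbeta(n, 2, 0.5)
  a_syn <- associate_burden(bt_syn, ph, cov, family = "linear")
  expect_gt(a_syn$p, 0.05)
  ## logistic separation is flagged, not silently dropped
  sep <- data.frame(sample_id = paste0("S", 1:40),
                    score = rep(c(0, 1), each = 20))
  ph_sep <- stats::setNames(rep(c(0, 1), each = 20), sep$sample_id)
  a_sep <- suppressWarnings(associate_burden(sep, ph_sep, family = "logistic"))
  expect_true(a_sep$separation)
  expect_error(associate_burden(bt, ph + 0.5, family = "logistic"), "binary")
})

test_that("Fisher gene tests agree with hypergeometric enumeration", {
  ## independent oracle: enumerate the conditional distribution directly
  fisher_oracle <- function(a, b, c_, d) {
    m <- a + c_; n <- b + d; k <- a + b
    lo <- max(0, k - n); hi <- min(k, m)
    pr <- stats::dhyper(lo:hi, m, n, k)
    sum(pr[pr <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  counts <- data.frame(gene = c("G1", "G2", "G3"), filter_combo = "stringent",
                       carriers_blood = c(10, 5, 7), n_blood = c(100, 100, 50),
                       carriers_cell = c(10, 0, 30), n_cell = c(100, 100, 50))
  res <- dna_source_gene_tests(counts)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 fisher_oracle(res$carriers_blood[i],
                               res$n_blood[i] - res$carriers_blood[i],
                               res$carriers_cell[i],
                               res$n_cell[i] - res$carriers_cell[i]),
                 tolerance = 1e-9)
  }
  expect_equal(res$p[res$gene == "G1"], 1)       # identical proportions
  expect_equal(unique(res$threshold), 0.05 / (18 * 3))
  ## zero-margin tables are uninformative
  z <- dna_source_gene_tests(data.frame(gene = "G0", filter_combo = "x",
                                        carriers_blood = 0, n_blood = 10,
                                        carriers_cell = 0, n_cell = 10))
  expect_equal(z$p, 1)
  ## injected cell-line excess concentrated in one gene ranks first
  set.seed(8)
  genes <- paste0("G", 1:30)
  cb <- rbinom(30, 200, 0.05)
  cc <- rbinom(30, 50, 0.05); cc[7] <- 30
  sim_counts <- data.frame(gene = genes, filter_combo = "stringent",
                           carriers_blood = cb, n_blood = 200,
                           carriers_cell = cc, n_cell = 50)
  ranked <- dna_source_gene_tests(sim_counts)
  expect_equal(ranked$gene[1], "G7")
})

test_that("DNA-source count regression recovers an injected excess", {
  set.seed(17)
  n_cell <- 150; n_blood <- 600
  counts <- data.frame(
    sample_id = paste0("S", seq_len(n_cell + n_blood)),
    count = c(rpois(n_cell, 7), rpois(n_blood, 5)),
    dna_source = c(rep("cell_line", n_cell), rep("blood", n_blood)),
    pc1 = rnorm(n_cell + n_blood), pc2 = rnorm(n_cell + n_blood),
    pc3 = rnorm(n_cell + n_blood))
  r <- dna_source_count_regression(counts)
  expect_lt(abs(r$excess - 2), 1.96 * r$se)
  expect_lt(r$p, 0.01)
  counts0 <- counts; counts0$count <- rpois(n_cell + n_blood, 5)
  expect_gt(dna_source_count_regression(counts0)$p, 0.001)
  expect_error(dna_source_count_regression(
    counts[counts$dna_source == "blood", ]), "both DNA sources")
})

test_that("prevalence test agrees with brute-force Poisson summation", {
  poisson_oracle <- function(obs, mu) {
    d <- stats::dpois(0:1000, mu)
    sum(d[d <= stats::dpois(obs, mu) * (1 + 1e-7)])
  }
  for (cse in list(c(3, 7), c(10, 7), c(0, 2), c(25, 20), c(50, 45))) {
    pr <- prevalence_test(10000, cse[1], cse[2] / 10000)
    expect_equal(pr$p, poisson_oracle(cse[1], cse[2]), tolerance = 1e-6)
  }
  ## observing the mode of the distribution gives p = 1
  pr1 <- prevalence_test(10000, 7, 7 / 10000)
  expect_equal(pr1$p, 1)
  expect_error(prevalence_test(0, 1, 0.01), "children")
  expect_error(prevalence_test(100, 1, 0), "incidence")
})

test_that("homozygote counting feeds the prevalence test end to end", {
  gt <- matrix(0L, 3, 6)
  gt[1, 1] <- 2L                      # child 1 hom pathogenic
  gt[2, 2] <- 1L                      # het only: not affected
  gt[3, 3] <- 2L                      # hom at a non-pathogenic site
  cs <- toy_callset(gt)
  ann <- data.frame(key = variant_keys(cs), gene = c("CFTR", "CFTR", "OTHER"),
                    consequence = "missense", cadd = 20, loftee_hc = 0,
                    s_het = 0.1, pathogenic = c(TRUE, TRUE, FALSE))
  pr <- genetic_prevalence(cs, ann, "CFTR", incidence = 1 / 3,
                           children = cs$samples$sample_id)
  expect_equal(pr$observed, 1)
  expect_equal(pr$expected, 2)
})
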