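test_that("discordance score is exact and honours the evaluability floor", {
  a <- rep(c(0L, 1L, 2L), length.out = 300)
  expect_equal(genotype_discordance(a, a, min_sites = 100)$score, 0)
  expect_equal(genotype_discordance(a, a, min_sites = 100)$verdict, "match")
  b <- a; b[1:2] <- 2L - b[1:2] # guaranteed different? make explicit below
  b <- a; b[1] <- ifelse(a[1] == 0L, 1L, 0L); b[2] <- ifelse(a[2] == 0L, 1L, 0L)
  d <- genotype_discordance(a[1:50], b[1:50], min_sites = 10)
  expect_equal(d$score, 2 / 50)
  expect_equal(d$verdict, "match")                  # 0.04 < 0.05
  expect_equal(genotype_discordance(a[1:50], b[1:50], min_sites = 51)$verdict,
               "unevaluable")
  ## missing genotypes drop out of the denominator
  a2 <- c(0L, NA, 1L, 2L); b2 <- c(1L, 0L, NA, 2L)
  expect_equal(genotype_discordance(a2, b2, min_sites = 1)$score, 0.5)
})

test_that("kinship estimates classify simulated relationships without error", {
  sim <- base_sim()
  cs <- sim$callset
  kin <- estimate_relatedness(cs)
  trios <- complete_trios(sim$pedigree, cs$samples$sample_id)
  po_pairs <- rbind(data.frame(a = trios$child, b = trios$mother),
                    data.frame(a = trios$child, b = trios$father))
  for (i in seq_len(nrow(po_pairs))) {
    hit <- (kin$id1 == po_pairs$a[i] & kin$id2 == po_pairs$b[i]) |
           (kin$id1 == po_pairs$b[i] & kin$id2 == po_pairs$a[i])
    expect_equal(kin$degree[hit], "parent_offspring")
  }
  expect_gte(min(kin$n_sites), 2000)
  unrel <- kin[substr(kin$id1, 1, 1) == "S" & substr(kin$id2, 1, 1) == "S", ]
  expect_true(all(unrel$degree == "unrelated"))
  expect_true(all(unrel$kinship < 0.0884))
  ## duplicated column: duplicate/MZ with near-0.5 kinship, near-0 IBS0
  dup <- subset_callset(cs, samples = c("S0001", "S0002"))
  dup$GT[, 2] <- dup$GT[, 1]
  kd <- estimate_relatedness(dup)
  expect_equal(kd$degree, "duplicate_mz")
  expect_gt(kd$kinship, 0.45)
  expect_lt(kd$ibs0, 0.001)
  expect_error(estimate_relatedness(subset_callset(cs, variants = which(
    site_frequencies(cs)$af == 0))), "monomorphic|common")
})

test_that("array mismatch scenarios i-iv resolve exactly as specified", {
  ped <- Pedigree(
    family_id = c("F1", "F1", "F1", "F2", "F2", "F3"),
    individual_id = c("mum", "dad", "kid", "twinA", "twinB", "solo"),
    father_id = c(NA, NA, "dad", NA, NA, NA),
    mother_id = c(NA, NA, "mum", NA, NA, NA),
    role = c("mother", "father", "child", "child", "child", "child"),
    twin_group = c(NA, NA, NA, "T1", "T1", NA))
  kin_ok <- data.frame(id1 = c("kid", "kid"), id2 = c("mum", "dad"),
                       kinship = 0.25, ibs0 = 0, n_sites = 5000,
                       degree = "parent_offspring")
  kin_bad <- transform(kin_ok, degree = "unrelated", kinship = 0.01)
  ids <- ped$individual_id
  mk_report <- function(sample_id, best) data.frame(
    sample_id = sample_id, status = "mismatch", score = 0.2, best_match = best,
    stringsAsFactors = FALSE)
  ## (i) no sequenced first-degree relative: remove
  r1 <- resolve_array_mismatches(mk_report("solo", "someone"), ped, kin_ok, ids)
  expect_equal(r1$outcome, "remove"); expect_equal(r1$scenario, "i")
  ## (ii) relatives present but relationship not as declared: remove
  r2 <- resolve_array_mismatches(mk_report("kid", "someone"), ped, kin_bad, ids)
  expect_equal(r2$outcome, "remove"); expect_equal(r2$scenario, "ii")
  ## (iii) relatives confirm: keep
  r3 <- resolve_array_mismatches(mk_report("kid", "someone"), ped, kin_ok, ids)
  expect_equal(r3$outcome, "keep"); expect_equal(r3$scenario, "iii")
  ## (iv) best match is the MZ twin of the expected sample: keep
  r4 <- resolve_array_mismatches(mk_report("twinA", "twinB"), ped, kin_bad, ids)
  expect_equal(r4$outcome, "keep"); expect_equal(r4$scenario, "iv")
  ## pedigree referencing absent samples behaves as scenario i
  r5 <- resolve_array_mismatches(mk_report("kid", "someone"), ped, kin_bad,
                                 sample_ids = c("kid", "solo"))
  expect_equal(r5$scenario, "i")
})

test_that("family-consistency removals follow the two-branch rule", {
  ped <- Pedigree(family_id = rep("F1", 3),
                  individual_id = c("mum", "dad", "kid"),
                  father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mum"),
                  role = c("mother", "father", "child"))
  ids <- ped$individual_id
  mk_kin <- function(mum_deg, dad_deg) data.frame(
    id1 = c("kid", "kid"), id2 = c("mum", "dad"),
    kinship = c(0.25, 0.25), ibs0 = 0, n_sites = 5000,
    degree = c(mum_deg, dad_deg), stringsAsFactors = FALSE)
  ## concordant trio: no removals
  expect_equal(nrow(family_consistency_filter(ped, mk_kin("parent_offspring",
    "parent_offspring"), ids)), 0)
  ## father fails, mother confirms: father removed only
  r <- family_consistency_filter(ped, mk_kin("parent_offspring", "unrelated"), ids)
  expect_identical(sort(r$sample_id), "dad")
  ## duo with no confirming member: both removed
  ped2 <- ped[ped$individual_id != "dad", ]
  kin2 <- data.frame(id1 = "kid", id2 = "mum", kinship = 0.01, ibs0 = 0.1,
                     n_sites = 5000, degree = "unrelated")
  r2 <- family_consistency_filter(ped2, kin2, c("mum", "kid"))
  expect_setequal(r2$sample_id, c("mum", "kid"))
})

test_that("duplicate resolution keeps twins and applies the 2-of-3 rule", {
  ped <- Pedigree(family_id = c("F1", "F1", "F2"),
                  individual_id = c("twinA", "twinB", "kid"),
                  role = "child", twin_group = c("T1", "T1", NA))
  q <- data.frame(sample_id = c("twinA", "twinB", "A", "A_D", "x", "y", "z"),
                  bait_coverage = c(80, 80, 90, 85, 80, 80, 80),
                  mean_depth_called = c(60, 60, 70, 65, 60, 60, 60),
                  genotyping_rate = c(0.99, 0.99, 0.98, 0.99, 0.99, 0.99, 0.99))
  ## twin pair kept
  r1 <- resolve_duplicates(data.frame(id1 = "twinA", id2 = "twinB",
                                      validated = TRUE, intentional = FALSE),
                           ped, q)
  expect_true(all(r1$outcome == "keep"))
  ## A wins coverage + depth, loses rate: keep A
  r2 <- resolve_duplicates(data.frame(id1 = "A", id2 = "A_D",
                                      validated = TRUE, intentional = TRUE),
                           ped, q)
  expect_equal(r2$outcome[r2$sample_id == "A"], "keep")
  expect_equal(r2$outcome[r2$sample_id == "A_D"], "remove")
  ## mutually-duplicate triplet with no validating evidence: all removed
  r3 <- resolve_duplicates(data.frame(id1 = c("x", "y", "x"),
                                      id2 = c("y", "z", "z"),
                                      validated = FALSE, intentional = FALSE),
                           ped, q)
  expect_equal(sort(r3$sample_id), c("x", "y", "z"))
  expect_true(all(r3$outcome == "remove"))
  ## full tie: deterministic lexicographic keep, logged
  r4 <- resolve_duplicates(data.frame(id1 = "z", id2 = "y",
                                      validated = TRUE, intentional = TRUE),
                           ped, q)
  expect_equal(r4$sample_id[r4$outcome == "keep"], "y")
  expect_match(r4$evidence[r4$outcome == "keep"], "tie")
})

test_that("sex-consistency removes conflicts and keeps undetermined", {
  reported <- data.frame(sample_id = c("a", "b", "c"),
                         reported_sex = c("F", "M", "F"))
  inferred <- data.frame(sample_id = c("a", "b", "c"),
                         inferred_sex = c("XY", "XY", "undetermined"))
  r <- sex_consistency(reported, inferred)
  expect_equal(r$outcome[r$sample_id == "a"], "remove")
  expect_equal(r$outcome[r$sample_id == "b"], "keep")
  expect_equal(r$outcome[r$sample_id == "c"], "keep")
  expect_match(r$evidence[r$sample_id == "c"], "flag")
})

test_that("injected swaps are caught by array checks and family rules", {
  cfg <- sim_config(n_families = 25, n_singletons = 12, n_sites = 3000,
                    seed = 53, swap_pairs = 2)
  clean <- simulate_cohort(cfg)
  sim <- inject_error_modes(clean)
  cs <- sim$callset
  swapped <- sim$labels$samples$sample_id[sim$labels$samples$status == "swapped"]
  ## array truth = pre-swap genotypes at common sites
  fr <- site_frequencies(clean$callset)
  common <- which(!is.na(fr$af) & fr$af >= 0.05 &
                  clean$callset$variants$variant_type == "snv")
  array_gt <- clean$callset$GT[common, , drop = FALSE]
  sub <- subset_callset(cs, variants = common)
  rep <- check_array_identity(sub, array_gt)
  expect_setequal(rep$sample_id[rep$status == "mismatch"], swapped)
  kin <- estimate_relatedness(cs)
  dec <- resolve_array_mismatches(rep, sim$pedigree, kin, cs$samples$sample_id)
  removed <- dec$sample_id[dec$outcome == "remove"]
  expect_setequal(removed, swapped)
  ## family consistency on the remaining samples: no false removals
  keep_ids <- setdiff(cs$samples$sample_id, removed)
  fc <- family_consistency_filter(sim$pedigree, kin, keep_ids)
  expect_equal(nrow(fc), 0)
  ## a parent swap without array data is caught by family rules alone
  par_swap <- swapped[swapped %in% sim$pedigree$individual_id[
    sim$pedigree$role %in% c("mother", "father")]]
  fc_all <- family_consistency_filter(sim$pedigree, kin, cs$samples$sample_id)
  expect_true(all(par_swap %in% fc_all$sample_id))
})

test_that("greedy unrelated selection removes all over-threshold links", {
  kin <- data.frame(id1 = c("a", "b", "a"), id2 = c("b", "c", "d"),
                    kinship = c(0.25, 0.25, 0.01), ibs0 = 0, n_sites = 5000,
                    degree = "parent_offspring")
  keep <- select_unrelated(c("a", "b", "c", "d"), kin)
  expect_true(!"b" %in% keep)               # b has two links: removed first
  expect_setequal(keep, c("a", "c", "d"))
})
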