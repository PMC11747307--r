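test_that("training labels apply hard filters with the stated precedence", {
  cs <- toy_callset(matrix(0L, 5, 1),
                    qd = c(1.5, 20, 20, 20, 1.0),
                    fs = c(5, 60.0, 61, 5, 5),
                    mq = c(60, 60, 60, 29, 60))
  truth <- c(FALSE, TRUE, FALSE, FALSE, TRUE)
  labs <- label_training_sites(cs, truth)
  expect_equal(labs[1], "negative")          # QD 1.5 < 2
  expect_equal(labs[2], "truth")             # FS = 60 exactly: not negative
  expect_equal(labs[3], "negative")          # FS > 60
  expect_equal(labs[4], "negative")          # MQ < 30
  expect_equal(labs[5], "negative")          # hard filter wins over truth set
})

test_that("features include the C>A indicator and mean het allele balance", {
  gt <- matrix(c(1L, 1L, 0L,
                 1L, 0L, 0L,
                 0L, 0L, 0L), 3, 3, byrow = TRUE)
  dp <- matrix(10L, 3, 3)
  ad <- matrix(c(5L, 4L, 0L,
                 5L, 0L, 0L,
                 0L, 0L, 0L), 3, 3, byrow = TRUE)
  cs <- toy_callset(gt, ref = c("G", "C", "C"), alt = c("T", "T", "A"),
                    dp = dp, gq = matrix(50L, 3, 3), ad = ad,
                    qd = c(10, 10, 10), fs = c(1, 1, 1), sor = c(1, 1, 1),
                    mq = c(60, 60, 60))
  ft <- extract_features(cs)
  expect_equal(ft$is_ca, c(1L, 0L, 1L))      # G>T yes, C>T no, C>A yes
  expect_equal(ft$mean_het_ab[1], mean(c(0.5, 0.4)))   # AD (5,5) and (6,4)
  expect_equal(ft$mean_het_ab[2], 0.5)
  ## site without hets: median-imputed with a missingness indicator
  expect_equal(ft$mean_het_ab_missing, c(0L, 0L, 1L))
  ## feature can be switched off for cohorts without the artefact
  expect_false("is_ca" %in% names(extract_features(cs, use_is_ca = FALSE)))
})

test_that("forest scoring separates labelled classes and is reproducible", {
  aux <- artefact_scores()
  sim <- artefact_sim()
  labs <- aux$labels
  expect_error(train_and_score(aux$features, rep("truth", nrow(aux$features)),
                               sim$callset$variants$contig),
               "both truth and negative")
  ## determinism under a fixed seed
  sc2 <- train_and_score(aux$features, labs, sim$callset$variants$contig,
                         seed = 5)
  expect_identical(sc2, aux$scores)
  ## artefact sites score clearly below truth sites
  art <- sim$labels$variants$label == "artefact"
  expect_gt(mean(aux$scores[labs == "truth"]), mean(aux$scores[art]) + 0.3)
  ## label permutation destroys the ranking signal: cumulative truth curve
  ## tracks the diagonal
  set.seed(99)
  perm_labs <- labs
  tr_idx <- which(sim$callset$variants$contig == "chr20" &
                  labs %in% c("truth", "negative"))
  perm_labs[tr_idx] <- sample(labs[tr_idx])
  sc_perm <- train_and_score(aux$features, perm_labs,
                             sim$callset$variants$contig, seed = 5)
  bins_perm <- bin_scores(sc_perm, variant_keys(sim$callset))
  curve <- cumulative_tp_fp(bins_perm, labs)
  dev <- max(abs(curve$truth_pct - seq_len(100)), na.rm = TRUE)
  expect_lt(dev, 20)
})

test_that("score binning is near-uniform with a deterministic tie policy", {
  keys <- sprintf("k%03d", 1:100)
  b1 <- bin_scores(seq(1, 0.01, length.out = 100), keys)
  expect_equal(sort(unique(b1)), 1:100)
  expect_equal(b1, 1:100)                       # descending scores: rank order
  b2 <- bin_scores(rep(0.5, 200), sprintf("k%03d", 1:200))
  expect_true(all(table(b2) == 2))
  expect_identical(b2, bin_scores(rep(0.5, 200), sprintf("k%03d", 1:200)))
  expect_error(bin_scores(c(1, NA), c("a", "b")), "finite")
})

test_that("cumulative curves are monotone, end at 100% and match a recount", {
  aux <- artefact_scores()
  curves <- cumulative_tp_fp(aux$bins, aux$labels)
  expect_equal(curves$truth_pct[100], 100)
  expect_equal(curves$negative_pct[100], 100)
  expect_true(all(diff(curves$truth_pct) >= 0))
  expect_true(all(diff(curves$negative_pct) >= 0))
  ## brute-force recount at a handful of bins
  for (b in c(10, 36, 84)) {
    expect_equal(curves$truth_pct[b],
                 100 * sum(aux$labels == "truth" & aux$bins <= b) /
                   sum(aux$labels == "truth"))
  }
  ## perfectly separating construction: truth done by bin 50
  labs <- rep(c("truth", "negative"), each = 100)
  bins <- bin_scores(c(seq(1, 0.9, length.out = 100),
                       seq(0.1, 0, length.out = 100)),
                     sprintf("k%03d", 1:200))
  cv <- cumulative_tp_fp(bins, labs)
  expect_equal(cv$truth_pct[50], 100)
  expect_equal(cv$negative_pct[50], 0)
})

test_that("profile application masks strictly, drops by rate, and is idempotent", {
  prof <- filter_profile("mcs_stringent",
    snv = list(max_bin = 82, min_dp = 5, min_gq = 15, min_het_ab = 0.2,
               min_rate = 0.5),
    indel = list(max_bin = 58, min_dp = 10, min_gq = 20, min_het_ab = 0.3,
                 min_rate = 0.5))
  ## het at exactly DP=5, GQ=15, AB=0.2 is retained (failures are strict <)
  cs <- toy_callset(matrix(c(1L, 1L), 2, 1),
                    dp = matrix(c(5L, 5L), 2, 1),
                    gq = matrix(c(15L, 14L), 2, 1),
                    ad = matrix(c(1L, 1L), 2, 1))
  ap <- apply_profile(cs, bins = c(1L, 1L), prof)
  expect_equal(unname(ap$callset$GT[1, 1]), 1L)
  expect_equal(nrow(ap$callset$variants), 1)      # row 2 masked -> rate 0 < 0.5
  ## genotyping-rate boundary: 49% drops at a 50% minimum
  gt <- matrix(1L, 1, 100); gt[1, 1:51] <- NA_integer_
  cs2 <- toy_callset(gt, dp = matrix(50L, 1, 100), gq = matrix(99L, 1, 100),
                     ad = matrix(25L, 1, 100))
  expect_false(apply_profile(cs2, 1L, prof)$variant_pass[1])
  gt[1, 51] <- 1L
  cs3 <- toy_callset(gt, dp = matrix(50L, 1, 100), gq = matrix(99L, 1, 100),
                     ad = matrix(25L, 1, 100))
  expect_true(apply_profile(cs3, 1L, prof)$variant_pass[1])
  ## idempotence on the artefact cohort
  sim <- artefact_sim(); aux <- artefact_scores()
  a1 <- apply_profile(sim$callset, aux$bins, prof)
  a2 <- apply_profile(a1$callset, a1$bins, prof)
  expect_identical(a2$callset$GT, a1$callset$GT)
  expect_true(all(a2$variant_pass))
  ## monotonicity: raising min DP never increases retained genotypes
  retained <- vapply(c(0, 5, 10, 20, 40), function(d) {
    p <- prof; p$snv$min_dp <- d; p$indel$min_dp <- d
    sum(!is.na(apply_profile(sim$callset, aux$bins, p)$callset$GT))
  }, 0)
  expect_true(all(diff(retained) <= 0))
})

test_that("transmitted/untransmitted counting matches its definition", {
  fx <- simulate_transmission_fixture(50, 400, seed = 3)
  tu <- tu_ratio(fx$callset, fx$pedigree, fx$annotation)
  expect_equal(tu$transmitted, sum(fx$transmitted))
  expect_equal(tu$untransmitted, sum(!fx$transmitted))
  expect_equal(tu$ratio, sum(fx$transmitted) / sum(!fx$transmitted))
  ## 3 transmitted of 6 -> ratio 1
  fx2 <- simulate_transmission_fixture(10, 6, seed = 11)
  gt <- fx2$callset$GT
  ped <- fx2$pedigree
  kids <- ped$individual_id[ped$role == "child"]
  ## force exactly 3 transmissions
  carrier_trio <- apply(gt[, ped$individual_id[ped$role != "child"]], 1,
                        function(r) which(r == 1L))
  for (i in 1:6) gt[i, kids] <- 0L
  for (i in 1:3) {
    tr_fam <- ped$family_id[ped$role != "child"][carrier_trio[i]]
    kid <- ped$individual_id[ped$role == "child" & ped$family_id == tr_fam]
    gt[i, kid] <- 1L
  }
  cs <- Callset(fx2$callset$samples, fx2$callset$variants, gt)
  tu2 <- tu_ratio(cs, ped, fx2$annotation)
  expect_equal(tu2$ratio, 1)
  ## a filter that preferentially masks child het calls drags the ratio down
  gt3 <- fx$callset$GT
  kids3 <- fx$pedigree$individual_id[fx$pedigree$role == "child"]
  set.seed(5)
  for (k in kids3) {
    hets <- which(gt3[, k] == 1L)
    gt3[hets[rbinom(length(hets), 1, 0.5) == 1], k] <- NA_integer_
  }
  tu3 <- tu_ratio(Callset(fx$callset$samples, fx$callset$variants, gt3),
                  fx$pedigree, fx$annotation)
  expect_lt(tu3$ratio, 1)
  expect_error(tu_ratio(subset_callset(fx$callset,
    samples = kids3), fx$pedigree, fx$annotation), "trio")
})

test_that("truth-sample evaluation scores exact allele matches", {
  gt <- matrix(c(1L, 2L, 0L, 1L), 4, 1, dimnames = list(NULL, "GIAB"))
  cs <- toy_callset(gt)
  colnames(cs$GT) <- "GIAB"; cs$samples$sample_id <- "GIAB"
  keys <- variant_keys(cs)
  ## retained calls exactly the truth list
  ev <- truth_sample_eval(cs, keys[c(1, 2, 4)], "GIAB")
  expect_equal(ev$precision, 1); expect_equal(ev$recall, 1)
  ## an extra truth entry lowers recall; a non-truth call lowers precision
  ev2 <- truth_sample_eval(cs, c(keys[c(1, 2)], "chr9:99:A:G"), "GIAB")
  expect_equal(ev2$tp, 2); expect_equal(ev2$fp, 1)
  expect_equal(ev2$precision, 2 / 3); expect_equal(ev2$recall, 2 / 3)
  ## empty retained set: precision flagged undefined, recall 0
  cs0 <- cs; cs0$GT[] <- 0L
  ev3 <- truth_sample_eval(cs0, keys[1], "GIAB")
  expect_true(is.na(ev3$precision)); expect_equal(ev3$recall, 0)
  expect_error(truth_sample_eval(cs, keys[1], "nope"), "absent")
})

test_that("grid evaluation reports consistent, monotone candidate metrics", {
  sim <- artefact_sim(); aux <- artefact_scores()
  mk <- function(bin, dp) filter_profile(paste0("b", bin, "_d", dp),
    snv = list(max_bin = bin, min_dp = dp, min_gq = 15, min_het_ab = 0.2,
               min_rate = 0.5),
    indel = list(max_bin = bin, min_dp = dp, min_gq = 20, min_het_ab = 0.3,
                 min_rate = 0.5))
  cands <- list(mk(95, 5), mk(84, 5), mk(60, 5), mk(84, 10))
  truth_id <- sim$callset$samples$sample_id[
    sim$callset$samples$role == "singleton"][1]
  truth_keys <- variant_keys(sim$callset)[
    !is.na(sim$callset$GT[, truth_id]) & sim$callset$GT[, truth_id] > 0 &
    sim$labels$variants$label == "real"]
  grid <- evaluate_grid(sim$callset, aux$bins, aux$labels, cands,
                        pedigree = sim$pedigree, annotation = sim$annotation,
                        truth_keys = truth_keys, truth_sample_id = truth_id)
  expect_equal(nrow(grid), 4)
  ## degenerate single-candidate grid row equals individually computed metrics
  one <- evaluate_grid(sim$callset, aux$bins, aux$labels, cands[2])
  ap <- apply_profile(sim$callset, aux$bins, cands[[2]])
  expect_equal(one$pct_truth_retained,
               100 * sum(ap$variant_pass & aux$labels == "truth") /
                 sum(aux$labels == "truth"))
  ## nested candidates: tightening the bin never increases negative retention
  expect_true(grid$pct_negative_retained[3] <= grid$pct_negative_retained[2])
  expect_true(grid$pct_negative_retained[2] <= grid$pct_negative_retained[1])
  ## percentages and rates live on their scales
  expect_true(all(grid$pct_truth_retained >= 0 & grid$pct_truth_retained <= 100))
  expect_true(all(grid$precision >= 0 & grid$precision <= 1, na.rm = TRUE))
})
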