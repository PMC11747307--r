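#' Pairwise genotype discordance
#'
#' Number of discordant genotype classes (hom-ref/het/hom-alt) divided by
#' the number of sites non-missing in both samples. A pair matches when the
#' score is strictly below `threshold` (0.05). Below `min_sites` shared
#' non-missing comparisons the verdict is `unevaluable` — conservative, not
#' a silent pass.
#'
#' @param a,b genotype dosage vectors over the same (biallelic SNV) sites.
#' @param threshold match cutoff on the discordance score.
#' @param min_sites minimum shared non-missing sites for a verdict.
#' @return List with `score`, `n_compared`, `verdict` in
#'   `{match, mismatch, unevaluable}`.
#' @export
genotype_discordance <- function(a, b, threshold = 0.05, min_sites = 200) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < min_sites) {
    return(list(score = NA_real_, n_compared = n, verdict = "unevaluable"))
  }
  score <- sum(a[ok] != b[ok]) / n
  list(score = score, n_compared = n,
       verdict = if (score < threshold) "match" else "mismatch")
}

#' Robust pairwise kinship and relationship degrees
#'
#' Within-pair robust kinship (no reliance on cohort allele frequencies):
#' `phi = (N_het,het - 2 N_IBS0) / (N_het,i + N_het,j)` over shared
#' non-missing biallelic SNVs with internal allele frequency >= `min_af`,
#' together with the IBS0 fraction (opposite homozygotes). Degrees follow
#' standard windows: duplicate/MZ for `phi > 0.354`; first-degree in
#' `(0.177, 0.354]`, split into parent-offspring (IBS0 < `po_ibs0`) versus
#' full siblings; second-degree in `(0.0884, 0.177]`; otherwise unrelated.
#'
#' @param callset A [Callset].
#' @param min_af minimum internal allele frequency of the sites used.
#' @param pairs optional two-column matrix/data.frame of sample ids to
#'   restrict to (default: all pairs).
#' @param po_ibs0 IBS0 bound separating parent-offspring from full sibs.
#' @param min_sites minimum shared sites for a classified estimate.
#' @return data.frame with `id1`, `id2`, `kinship`, `ibs0`, `n_sites`,
#'   `degree`.
#' @export
estimate_relatedness <- function(callset, min_af = 0.05, pairs = NULL,
                                 po_ibs0 = 0.005, min_sites = 200) {
  fr <- site_frequencies(callset)
  use <- callset$variants$contig %in% .AUTOSOMES &
         callset$variants$variant_type == "snv" & !is.na(fr$af) &
         pmin(fr$af, 1 - fr$af) >= min_af
  if (!any(use)) stop("no common variants available (monomorphic input?)")
  gt <- callset$GT[use, , drop = FALSE]
  M <- !is.na(gt)
  H <- (gt == 1L); H[!M] <- FALSE
  A <- (gt == 0L); A[!M] <- FALSE
  B <- (gt == 2L); B[!M] <- FALSE
  storage.mode(H) <- storage.mode(A) <- storage.mode(B) <- "numeric"
  Mn <- M; storage.mode(Mn) <- "numeric"
  hethet <- crossprod(H)
  ibs0 <- crossprod(A, B) + crossprod(B, A)
  het_shared <- crossprod(H, Mn)          # het in i over sites shared with j
  shared <- crossprod(Mn)
  ids <- callset$samples$sample_id
  if (is.null(pairs)) {
    cmb <- utils::combn(seq_along(ids), 2)
    pairs_idx <- cbind(cmb[1, ], cmb[2, ])
  } else {
    pairs_idx <- cbind(match(pairs[[1]], ids), match(pairs[[2]], ids))
  }
  i <- pairs_idx[, 1]; j <- pairs_idx[, 2]
  denom <- het_shared[cbind(i, j)] + het_shared[cbind(j, i)]
  phi <- (hethet[cbind(i, j)] - 2 * ibs0[cbind(i, j)]) / denom
  ibs0_frac <- ibs0[cbind(i, j)] / shared[cbind(i, j)]
  n_sites <- shared[cbind(i, j)]
  phi_c <- ifelse(is.finite(phi), phi, -1)
  degree <- rep("unrelated", length(phi))
  degree[phi_c > 0.0884] <- "second_degree"
  degree[phi_c > 0.177] <- ifelse(ibs0_frac[phi_c > 0.177] < po_ibs0,
                                  "parent_offspring", "full_sib")
  degree[phi_c > 0.354] <- "duplicate_mz"
  degree[!is.finite(phi) | n_sites < min_sites] <- "unevaluable"
  data.frame(id1 = ids[i], id2 = ids[j], kinship = phi, ibs0 = ibs0_frac,
             n_sites = n_sites, degree = degree, stringsAsFactors = FALSE)
}

.pair_degree <- function(kinship, a, b) {
  hit <- (kinship$id1 == a & kinship$id2 == b) |
         (kinship$id1 == b & kinship$id2 == a)
  if (!any(hit)) return(NA_character_)
  kinship$degree[which(hit)[1]]
}

#' Check exome samples against array genotypes
#'
#' Computes the discordance of each exome sample against its expected array
#' sample at shared sites and, when that fails the 0.05 match bound, against
#' every array sample to find the best match. Samples without array data
#' are reported `no_array`.
#'
#' @param callset A [Callset].
#' @param array_gt genotype dosage matrix (same variant rows as `callset`,
#'   columns named by array sample id).
#' @param expected named vector mapping exome sample id to expected array
#'   sample id (default: identical ids).
#' @param threshold,min_sites passed to [genotype_discordance()].
#' @return data.frame with per-sample `status` in
#'   `{match, mismatch, unevaluable, no_array}`, `score` and `best_match`.
#' @export
check_array_identity <- function(callset, array_gt, expected = NULL,
                                 threshold = 0.05, min_sites = 200) {
  ids <- callset$samples$sample_id
  if (is.null(expected)) expected <- stats::setNames(ids, ids)
  out <- data.frame(sample_id = ids, status = "no_array", score = NA_real_,
                    best_match = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    exp_id <- expected[ids[k]]
    if (is.na(exp_id) || !exp_id %in% colnames(array_gt)) next
    d <- genotype_discordance(callset$GT[, k], array_gt[, exp_id],
                              threshold, min_sites)
    out$score[k] <- d$score
    if (d$verdict == "unevaluable") { out$status[k] <- "unevaluable"; next }
    if (d$verdict == "match") { out$status[k] <- "match"; out$best_match[k] <- exp_id; next }
    out$status[k] <- "mismatch"
    scores <- vapply(colnames(array_gt), function(aid)
      genotype_discordance(callset$GT[, k], array_gt[, aid],
                           threshold, min_sites)$score, 0)
    if (any(!is.na(scores))) out$best_match[k] <- names(which.min(scores))
  }
  out
}

#' Resolve array-identity mismatches by pedigree and kinship
#'
#' Implements the four decision scenarios for an exome sample whose best
#' array match is not the expected sample: (i) no expected first-degree
#' relative is available in the exome data to confirm identity — remove;
#' (ii) relatives are present but the inferred genetic relationship is not
#' as declared — remove; (iii) the sample shows the expected relatedness to
#' its declared first-degree relatives — keep (the mix-up is assumed to be
#' in the array data); (iv) the best match is the monozygotic twin of the
#' expected sample — keep.
#'
#' @param array_report output of [check_array_identity()].
#' @param pedigree A [Pedigree] (twin groups mark MZ twins).
#' @param kinship output of [estimate_relatedness()].
#' @param sample_ids samples present in the exome callset.
#' @return data.frame of identity decisions with scenario codes.
#' @export
resolve_array_mismatches <- function(array_report, pedigree, kinship,
                                     sample_ids) {
  mm <- array_report[array_report$status == "mismatch", , drop = FALSE]
  fd <- declared_first_degree(pedigree)
  decisions <- list()
  expected_degree <- c(parent_offspring = "parent_offspring",
                       full_sib = "full_sib")
  for (k in seq_len(nrow(mm))) {
    id <- mm$sample_id[k]
    best <- mm$best_match[k]
    ## scenario iv: best hit is the MZ twin of the expected sample
    twin_of <- function(x) {
      tg <- pedigree$twin_group[pedigree$individual_id == x]
      if (!length(tg) || is.na(tg[1])) return(character())
      setdiff(pedigree$individual_id[!is.na(pedigree$twin_group) &
                                     pedigree$twin_group == tg[1]], x)
    }
    if (!is.na(best) && best %in% twin_of(id)) {
      decisions[[length(decisions) + 1L]] <- data.frame(
        sample_id = id, check = "array_match", outcome = "keep",
        scenario = "iv", evidence = paste0("best_match=", best, " (MZ twin)"),
        stringsAsFactors = FALSE)
      next
    }
    rel <- fd[(fd$id1 == id | fd$id2 == id), , drop = FALSE]
    other <- ifelse(rel$id1 == id, rel$id2, rel$id1)
    present <- other %in% sample_ids
    if (!any(present)) {
      decisions[[length(decisions) + 1L]] <- data.frame(
        sample_id = id, check = "array_match", outcome = "remove",
        scenario = "i", evidence = "no sequenced first-degree relative",
        stringsAsFactors = FALSE)
      next
    }
    rel <- rel[present, , drop = FALSE]; other <- other[present]
    obs <- vapply(other, function(o) .pair_degree(kinship, id, o), "")
    exp_deg <- expected_degree[rel$relation]
    exp_deg[rel$mz_twin] <- "duplicate_mz"
    ok <- !is.na(obs) & obs == exp_deg
    if (all(ok)) {
      decisions[[length(decisions) + 1L]] <- data.frame(
        sample_id = id, check = "array_match", outcome = "keep",
        scenario = "iii",
        evidence = paste0("relatedness confirmed: ", paste(other, collapse = ",")),
        stringsAsFactors = FALSE)
    } else {
      decisions[[length(decisions) + 1L]] <- data.frame(
        sample_id = id, check = "array_match", outcome = "remove",
        scenario = "ii",
        evidence = paste0("relatedness not as declared: ",
                          paste(other[!ok], collapse = ",")),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(decisions)) {
    return(data.frame(sample_id = character(), check = character(),
                      outcome = character(), scenario = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, decisions)
}

#' Remove family members with discordant inferred relatedness
#'
#' For each declared parent-offspring pair present in the callset whose
#' inferred degree is not parent-offspring (MZ-duplicate also fails): remove
#' both child and parent when no other family member confirms the child's
#' relationships; remove only the parent when the other parent shows the
#' expected relationship to the child. Fully concordant families yield no
#' removals.
#'
#' @param pedigree A [Pedigree].
#' @param kinship output of [estimate_relatedness()].
#' @param sample_ids samples present in the callset.
#' @return data.frame of identity decisions (`outcome = "remove"` rows only).
#' @export
family_consistency_filter <- function(pedigree, kinship, sample_ids) {
  decisions <- list()
  add <- function(id, why) {
    decisions[[length(decisions) + 1L]] <<- data.frame(
      sample_id = id, check = "family_relatedness", outcome = "remove",
      scenario = NA_character_, evidence = why, stringsAsFactors = FALSE)
  }
  kids <- pedigree[pedigree$role == "child" &
                   pedigree$individual_id %in% sample_ids, , drop = FALSE]
  for (k in seq_len(nrow(kids))) {
    cid <- kids$individual_id[k]
    parents <- c(mother = kids$mother_id[k], father = kids$father_id[k])
    parents <- parents[!is.na(parents) & parents %in% sample_ids]
    if (!length(parents)) next
    deg <- vapply(parents, function(p) .pair_degree(kinship, cid, p), "")
    bad <- !is.na(deg) & deg != "parent_offspring"
    if (!any(bad)) next
    good <- !is.na(deg) & deg == "parent_offspring"
    for (p in parents[bad]) {
      if (any(good)) {
        add(p, paste0("not parent-offspring with ", cid,
                      "; other parent confirms child"))
      } else {
        add(p, paste0("not parent-offspring with ", cid, "; unconfirmed pair"))
        add(cid, paste0("not parent-offspring with ", p, "; unconfirmed pair"))
      }
    }
  }
  if (!length(decisions)) {
    return(data.frame(sample_id = character(), check = character(),
                      outcome = character(), scenario = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, decisions)
  out[!duplicated(out$sample_id), , drop = FALSE]
}

#' Resolve genetic duplicate samples
#'
#' Declared monozygotic twins are kept. Intentional duplicates (two
#' sequencing runs of one individual) are resolved by keeping the sample
#' that wins at least two of three quality comparisons: average bait
#' coverage, average depth at called sites, genotyping rate; an all-three
#' tie breaks deterministically on the lexicographically smaller sample id
#' (logged). Duplicate groups with discordant identifiers and no validating
#' evidence are removed entirely.
#'
#' @param dup_pairs data.frame with `id1`, `id2` (duplicate/MZ pairs from
#'   kinship) and logical `validated` (identity confirmed by array data or
#'   relatives; unvalidated discordant groups are removed wholesale) and
#'   logical `intentional` (same declared individual, re-sequenced).
#' @param pedigree A [Pedigree].
#' @param quality data.frame with `sample_id`, `bait_coverage`,
#'   `mean_depth_called`, `genotyping_rate`.
#' @return data.frame of identity decisions covering every involved sample.
#' @export
resolve_duplicates <- function(dup_pairs, pedigree, quality) {
  decisions <- list()
  add <- function(id, outcome, why) {
    decisions[[length(decisions) + 1L]] <<- data.frame(
      sample_id = id, check = "duplicate", outcome = outcome,
      scenario = NA_character_, evidence = why, stringsAsFactors = FALSE)
  }
  is_mz <- function(a, b) {
    ta <- pedigree$twin_group[pedigree$individual_id == a]
    tb <- pedigree$twin_group[pedigree$individual_id == b]
    length(ta) && length(tb) && !is.na(ta[1]) && !is.na(tb[1]) && ta[1] == tb[1]
  }
  ## build connected duplicate groups so unvalidated triplets die together
  ids <- unique(c(dup_pairs$id1, dup_pairs$id2))
  grp <- stats::setNames(seq_along(ids), ids)
  for (k in seq_len(nrow(dup_pairs))) {
    g <- min(grp[dup_pairs$id1[k]], grp[dup_pairs$id2[k]])
    grp[grp == grp[dup_pairs$id1[k]] | grp == grp[dup_pairs$id2[k]]] <- g
  }
  for (g in unique(grp)) {
    members <- names(grp)[grp == g]
    prs <- dup_pairs[dup_pairs$id1 %in% members, , drop = FALSE]
    if (length(members) == 2 && is_mz(members[1], members[2])) {
      for (m in members) add(m, "keep", "declared MZ twin pair")
      next
    }
    validated <- if (!is.null(prs$validated)) all(prs$validated) else TRUE
    intentional <- if (!is.null(prs$intentional)) all(prs$intentional) else TRUE
    if (!validated || !intentional || length(members) > 2) {
      for (m in members) add(m, "remove",
                             "duplicate group without validating evidence")
      next
    }
    q <- quality[match(members, quality$sample_id), , drop = FALSE]
    wins <- integer(2)
    for (mc in c("bait_coverage", "mean_depth_called", "genotyping_rate")) {
      if (q[[mc]][1] > q[[mc]][2]) wins[1] <- wins[1] + 1L
      else if (q[[mc]][2] > q[[mc]][1]) wins[2] <- wins[2] + 1L
    }
    keep_i <- if (wins[1] >= 2) 1L else if (wins[2] >= 2) 2L else
      order(members)[1]  # deterministic lexicographic tie-break
    tie <- wins[1] < 2 && wins[2] < 2
    add(members[keep_i], "keep",
        paste0("wins ", wins[keep_i], "/3 quality comparisons",
               if (tie) "; tie broken on sample id" else ""))
    add(members[-keep_i], "remove",
        paste0("loses quality comparison (", wins[-keep_i], "/3)"))
  }
  if (!length(decisions)) {
    return(data.frame(sample_id = character(), check = character(),
                      outcome = character(), scenario = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, decisions)
}

#' Remove samples with reported/inferred sex conflicts
#'
#' A reported sex that conflicts with a confident XX/XY inference is
#' removed; an undetermined inference keeps the sample with a flag.
#'
#' @param reported data.frame with `sample_id` and `reported_sex`
#'   ("M"/"F").
#' @param inferred output of [infer_sex()].
#' @return data.frame of identity decisions.
#' @export
sex_consistency <- function(reported, inferred) {
  m <- merge(reported[, c("sample_id", "reported_sex")],
             inferred[, c("sample_id", "inferred_sex")], by = "sample_id")
  expected <- ifelse(m$reported_sex == "M", "XY", "XX")
  outcome <- ifelse(m$inferred_sex == "undetermined", "keep",
             ifelse(m$inferred_sex == expected, "keep", "remove"))
  data.frame(sample_id = m$sample_id, check = "sex",
             outcome = outcome,
             scenario = NA_character_,
             evidence = ifelse(m$inferred_sex == "undetermined",
                               "sex undetermined; kept with flag",
                               paste0("reported=", m$reported_sex,
                                      " inferred=", m$inferred_sex)),
             stringsAsFactors = FALSE)
}

#' Greedy selection of maximally unrelated samples
#'
#' Iteratively removes the sample with the most relatedness links above the
#' kinship threshold until no linked pair remains (ties broken on sample
#' id), yielding a maximal set with pairwise kinship below the bound.
#'
#' @param ids candidate sample ids.
#' @param kinship output of [estimate_relatedness()].
#' @param threshold kinship bound (default 0.0884, the second-degree lower
#'   bound).
#' @return Character vector of retained ids.
#' @export
select_unrelated <- function(ids, kinship, threshold = 0.0884) {
  edges <- kinship[kinship$id1 %in% ids & kinship$id2 %in% ids &
                   is.finite(kinship$kinship) &
                   kinship$kinship > threshold, c("id1", "id2")]
  keep <- ids
  while (nrow(edges)) {
    degcnt <- table(factor(c(edges$id1, edges$id2), levels = keep))
    worst <- names(degcnt)[order(-degcnt, names(degcnt))][1]
    keep <- setdiff(keep, worst)
    edges <- edges[edges$id1 != worst & edges$id2 != worst, , drop = FALSE]
  }
  keep
}
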