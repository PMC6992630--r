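test_that("CDR3 trimming removes 3 N-terminal and 2 C-terminal residues", {
  expect_equal(trim_cdr3("CASSLGQAYEQYF"), "SLGQAYEQ")
  expect_true(is.na(trim_cdr3("CASQYF")))          # 6-mer excluded
  expect_equal(trim_cdr3("CASSLYF"), "SL")          # minimum length 7
  expect_equal(trim_cdr3(c("CASSLGQAYEQYF", "CASQYF")),
               c("SLGQAYEQ", NA))
})

test_that("a planted motif absent from the reference is strongly enriched", {
  set.seed(41)
  ref <- random_cdr3s(2000, exclude = "WQRS")
  analysis <- c(vapply(1:10, function(i)
    paste0("CASS", "WQRS", paste(sample(AA20_test(), 5, TRUE), collapse = ""), "F"),
    character(1)), random_cdr3s(40, exclude = "WQRS"))
  mh <- enriched_motifs(analysis, ref, seed = 7)
  expect_true("WQRS" %in% mh$motif)
  row <- mh[mh$motif == "WQRS", ]
  expect_gte(row$fold_enrichment, 10)
  expect_lte(row$resample_p, 0.001)
  expect_equal(row$observed_count, 10L)
})

test_that("singleton k-mers are never tested and empty references fail", {
  set.seed(42)
  ref <- random_cdr3s(500)
  one <- c("CASSWWWWWTTTF", random_cdr3s(20, exclude = "WWWW"))
  mh <- enriched_motifs(one, ref, seed = 3)
  expect_false("WWWW" %in% mh$motif)   # support 1 < 2
  expect_error(enriched_motifs(one, character(0)), "empty reference")
})

test_that("an analysis set drawn from the reference yields few motifs", {
  set.seed(43)
  ref <- random_cdr3s(3000)
  analysis <- sample(ref, 150)
  mh <- suppressWarnings(enriched_motifs(analysis, ref, seed = 11))
  # null case: calls should stay near the false-positive rate over the
  # candidate k-mers actually tested
  trimmed <- substr(analysis, 4, nchar(analysis) - 2)
  n_cand <- 0
  for (k in 2:4) {
    km <- unlist(lapply(trimmed, function(s) {
      L <- nchar(s); if (L < k) return(character(0))
      unique(substring(s, 1:(L - k + 1), k:L))
    }))
    n_cand <- n_cand + sum(table(km) >= 2)
  }
  expect_lte(nrow(mh), max(3, 0.005 * n_cand))
})

test_that("groups are the connected components of the sharing relation", {
  tab <- data.frame(
    cdr3_aa = c("CASSAQRSTAYEQYF", "CASSBQRSTGYEQYF", "CASSCQRSTHYEQYF",
                "CASSLGQAYEQYF", "CASSLGQAYEGYF",
                "CASSZZZZZZTTF"),
    patient_id = "P1", sample_id = "S1", compartment = "TUMOR",
    stringsAsFactors = FALSE)
  gr <- build_groups(tab, "QRST")
  gid <- stats::setNames(gr$groups$group_id, gr$groups$cdr3_aa)
  # motif rule joins the three QRST carriers
  expect_equal(length(unique(gid[tab$cdr3_aa[1:3]])), 1)
  # global rule joins the Hamming-1 pair (no shared enriched motif)
  expect_equal(length(unique(gid[tab$cdr3_aa[4:5]])), 1)
  expect_false(gid[[tab$cdr3_aa[1]]] == gid[[tab$cdr3_aa[4]]])
  # singleton discarded
  expect_false("CASSZZZZZZTTF" %in% gr$groups$cdr3_aa)
})

test_that("grouping is order-invariant and matches a brute-force closure", {
  set.seed(44)
  fam1 <- paste0("CAS", replicate(6, paste(sample(AA20_test(), 3, TRUE),
                 collapse = "")), "PQRS",
                 replicate(6, paste(sample(AA20_test(), 3, TRUE), collapse = "")), "F")
  fam2 <- paste0("CAS", replicate(5, paste(sample(AA20_test(), 3, TRUE),
                 collapse = "")), "WYLK",
                 replicate(5, paste(sample(AA20_test(), 3, TRUE), collapse = "")), "F")
  noise <- random_cdr3s(40, exclude = c("PQRS", "WYLK"))
  seqs <- c(fam1, fam2, noise)
  tab <- data.frame(cdr3_aa = seqs, patient_id = "P1", sample_id = "S1",
                    compartment = "TUMOR", stringsAsFactors = FALSE)
  motifs <- c("PQRS", "WYLK")
  gr1 <- build_groups(tab, motifs)
  gr2 <- build_groups(tab[sample(nrow(tab)), ], motifs)
  part <- function(gr) {
    sp <- split(gr$groups$cdr3_aa, gr$groups$group_id)
    unname(lapply(sp, sort)[order(vapply(sp, min, character(1)))])
  }
  expect_equal(part(gr1), part(gr2))
  # brute-force oracle: transitive closure of the pairwise relation
  tr <- trim_cdr3(seqs)
  rel <- outer(seq_along(seqs), seq_along(seqs), Vectorize(function(i, j) {
    if (i == j) return(TRUE)
    shared_motif <- any(vapply(motifs, function(m)
      grepl(m, tr[i], fixed = TRUE) && grepl(m, tr[j], fixed = TRUE),
      logical(1)))
    ham1 <- nchar(tr[i]) == nchar(tr[j]) &&
      sum(strsplit(tr[i], "")[[1]] != strsplit(tr[j], "")[[1]]) <= 1
    shared_motif || ham1
  }))
  reach <- rel
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- apply(reach, 1, function(r) min(which(r)))
  oracle <- split(seqs, comp)
  oracle <- lapply(oracle[vapply(oracle, function(s)
    length(unique(s)) >= 2, logical(1))], function(s) sort(unique(s)))
  oracle <- unname(oracle[order(vapply(oracle, min, character(1)))])
  expect_equal(part(gr1), oracle)
})

test_that("viral classification needs 3 reference matches and V-gene bias", {
  mk_groups <- function(v_genes, n_match) {
    seqs <- paste0("CASSM", sprintf("%02d", seq_along(v_genes)), "AQRSTYEQYF")
    tab <- data.frame(cdr3_aa = seqs, v_gene = v_genes, patient_id = "P1",
                      sample_id = "S1", compartment = "TUMOR",
                      stringsAsFactors = FALSE)
    gr <- build_groups(tab, "QRST")
    ref <- data.frame(cdr3_aa = c(seqs[seq_len(n_match)], "CASSDECOYAAF"),
                      v_gene = "TRBV9", epitope = "EPI")
    list(gr = gr, ref = ref)
  }
  usage <- stats::setNames(rep(40L, 20), paste0("TRBV", 1:20))
  usage["TRBV9"] <- 40L
  # 3 matches + strong V bias (5/5 TRBV9 vs 40/800 cohort-wide)
  g1 <- mk_groups(rep("TRBV9", 5), 3)
  r1 <- classify_viral(g1$gr, g1$ref, usage)
  expect_true(r1$is_viral)
  expect_lt(r1$v_gene_fisher_p, 0.05)
  # only 2 matches: not viral despite V bias
  g2 <- mk_groups(rep("TRBV9", 5), 2)
  expect_false(classify_viral(g2$gr, g2$ref, usage)$is_viral)
  # 3 matches but V usage mirroring the cohort: not viral
  g3 <- mk_groups(paste0("TRBV", 1:5), 3)
  r3 <- classify_viral(g3$gr, g3$ref, usage)
  expect_false(r3$is_viral)
  expect_gte(r3$v_gene_fisher_p, 0.05)
})

test_that("adding a viral member never turns a viral group non-viral", {
  usage <- stats::setNames(rep(30L, 10), paste0("TRBV", 1:10))
  seqs <- paste0("CASSM", sprintf("%02d", 1:6), "AQRSTYEQYF")
  tab <- data.frame(cdr3_aa = seqs, v_gene = "TRBV3", patient_id = "P1",
                    sample_id = "S1", compartment = "TUMOR",
                    stringsAsFactors = FALSE)
  gr <- build_groups(tab, "QRST")
  for (n_match in 3:6) {
    ref <- data.frame(cdr3_aa = seqs[seq_len(n_match)], v_gene = "TRBV3",
                      epitope = "EPI")
    expect_true(classify_viral(gr, ref, usage)$is_viral)
  }
})

test_that("location proportions normalize viral and non-viral separately", {
  mk <- function(gid, comp) data.frame(
    group_id = gid, cdr3_aa = paste0("CASS", gid, comp, "F"),
    v_gene = "TRBV9", patient_id = "P1", sample_id = paste0("P1_", comp),
    compartment = comp, stringsAsFactors = FALSE)
  members <- rbind(
    mk("V1", "TUMOR"), mk("V2", "ADJACENT_LUNG"),
    mk("V3", "TUMOR"), mk("V3", "ADJACENT_LUNG"),
    mk("V4", "TUMOR"), mk("V4", "ADJACENT_LUNG"),
    do.call(rbind, lapply(paste0("N", 1:6), mk, comp = "TUMOR")),
    mk("N7", "ADJACENT_LUNG"), mk("N8", "ADJACENT_LUNG"),
    mk("N9", "TUMOR"), mk("N9", "ADJACENT_LUNG"),
    mk("N10", "TUMOR"), mk("N10", "ADJACENT_LUNG"))
  groups <- structure(list(groups = unique(members[, c("group_id", "cdr3_aa")]),
                           members = members, motifs_by_group = list()),
                      class = "specificity_groups")
  calls <- data.frame(group_id = c(paste0("V", 1:4), paste0("N", 1:10)),
                      is_viral = rep(c(TRUE, FALSE), c(4, 10)))
  lp <- location_proportions(groups, calls, "P1")
  expect_equal(unname(lp$viral), c(0.25, 0.25, 0.5))
  expect_equal(unname(lp$nonviral), c(0.6, 0.2, 0.2))
  expect_equal(lp$fold_shared, 2.5)
  # all-shared viral groups
  calls2 <- calls; members2 <- members[members$group_id %in%
    c("V3", "V4", "N9", "N10", "N1"), ]
  groups2 <- structure(list(groups = unique(members2[, c("group_id", "cdr3_aa")]),
                            members = members2, motifs_by_group = list()),
                       class = "specificity_groups")
  lp2 <- location_proportions(groups2, calls2, "P1")
  expect_equal(unname(lp2$viral[["SHARED"]]), 1)
  # unknown patient: absent results
  lp3 <- location_proportions(groups, calls, "P99")
  expect_null(lp3$viral)
  expect_true(is.na(lp3$fold_shared))
})
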