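# Pairwise identity, family clustering, center-star alignment and PFMs.

test_that("pairwise identity behaves on canonical toy pairs", {
  s <- random_protein(40)
  expect_equal(pairwise_identity(s, s), 100)
  expect_equal(pairwise_identity(strrep("A", 20), strrep("V", 25)), 0)
  # best global alignment of AAAA vs AATA is gap-free: 3/4 identical
  expect_equal(pairwise_identity("AAAA", "AATA"), 75)
  expect_equal(pairwise_identity("AAAA", "AATA"),
               pairwise_identity("AATA", "AAAA"))
  expect_error(pairwise_identity("", "AA"), "empty")
})

test_that("the identity matrix is symmetric with a 100 diagonal", {
  set.seed(41)
  seqs <- stats::setNames(vapply(1:6, function(i) random_protein(60), ""),
                          sprintf("p%d", 1:6))
  im <- build_identity_matrix(seqs)
  expect_equal(im, t(im), tolerance = 1e-12)
  expect_equal(unname(diag(im)), rep(100, 6))
  expect_true(all(im >= 0 & im <= 100))
  # pairwise entries agree with the scalar routine
  expect_equal(im["p2", "p5"], pairwise_identity(seqs["p2"], seqs["p5"]))
  expect_error(build_identity_matrix(stats::setNames(seqs, rep("p", 6))),
               "unique")
  three <- stats::setNames(rep(strrep("QSA", 15), 3), c("a", "b", "c"))
  expect_true(all(build_identity_matrix(three) == 100))
})

test_that("single-linkage clustering follows threshold and size rules", {
  ids <- sprintf("p%d", 1:6)
  im <- matrix(10, 6, 6, dimnames = list(ids, ids)); diag(im) <- 100
  all_single <- cluster_families(im)
  expect_true(all(all_single$assignment == "singleton"))
  expect_length(all_single$families, 0)

  im2 <- im
  im2[1:5, 1:5] <- 90; diag(im2) <- 100
  out <- cluster_families(im2)
  expect_length(out$families, 1)
  expect_identical(out$families$F1, ids[1:5])
  expect_identical(unname(out$assignment[6]), "singleton")
})

test_that("family labels are stable under input permutation", {
  cfg <- small_cfg(seed = 14)
  sim <- gen_timecourse(cfg)
  prot <- gen_proteome(cfg, sim$truth)
  tr <- sim$truth
  fam_ids <- tr$gene_id[!is.na(tr$family)]
  mature <- trim_signal_peptide(
    stats::setNames(as.character(prot$proteins[fam_ids]), fam_ids))
  im <- build_identity_matrix(mature)
  a <- cluster_families(im)
  perm <- sample(seq_along(fam_ids))
  b <- cluster_families(im[perm, perm])
  expect_identical(a$families, b$families)
  expect_identical(a$assignment[fam_ids], b$assignment[fam_ids])
})

test_that("planted families separate from unrelated proteins in identity", {
  cfg <- small_cfg(seed = 15, family_mutation_rate = 0.1)
  sim <- gen_timecourse(cfg)
  prot <- gen_proteome(cfg, sim$truth)
  tr <- sim$truth
  fam_ids <- tr$gene_id[!is.na(tr$family)]
  other <- setdiff(tr$gene_id[tr$secreted], fam_ids)[1:5]
  ids <- c(fam_ids, other)
  mature <- trim_signal_peptide(
    stats::setNames(as.character(prot$proteins[ids]), ids))
  im <- build_identity_matrix(mature)
  fl <- c(tr$family[match(fam_ids, tr$gene_id)], rep("bg", 5))
  same <- outer(fl, fl, "==") & upper.tri(im)
  fam_pair <- outer(fl != "bg", fl != "bg", "&")
  within <- im[same & fam_pair]
  between <- im[!same & upper.tri(im)]
  expect_gt(mean(within), mean(between))
  expect_gt(min(within), max(between))
})

test_that("center-star alignment round-trips every sequence", {
  aln <- center_star_msa(c(a = "ACD", b = "AD"))
  expect_identical(unique(nchar(aln)), 3L)
  expect_identical(sum(vapply(strsplit(aln, ""), function(x)
    sum(x == "-"), 0L)), 1L)
  expect_identical(gsub("-", "", aln[["a"]]), "ACD")
  expect_identical(gsub("-", "", aln[["b"]]), "AD")

  same <- stats::setNames(rep(strrep("QNA", 10), 3), c("x", "y", "z"))
  aln2 <- center_star_msa(same)
  expect_false(any(grepl("-", aln2, fixed = TRUE)))

  cfg <- small_cfg(seed = 16)
  sim <- gen_timecourse(cfg)
  prot <- gen_proteome(cfg, sim$truth)
  tr <- sim$truth
  f1 <- tr$gene_id[!is.na(tr$family) & tr$family == "F1"]
  mature <- trim_signal_peptide(
    stats::setNames(as.character(prot$proteins[f1]), f1))
  aln3 <- center_star_msa(mature)
  expect_length(unique(nchar(aln3)), 1)
  for (id in f1)
    expect_identical(gsub("-", "", aln3[[id]]), unname(mature[id]))
})

test_that("PFM columns sum to one including the gap fraction", {
  pfm <- position_frequency_matrix(c(a = "QQ-", b = "QN-", c = "Q-A"))
  expect_equal(unname(colSums(pfm)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(pfm["Q", 1]), 1)
  expect_equal(unname(pfm["Q", 2]), 1 / 3)
  expect_equal(unname(pfm["N", 2]), 1 / 3)
  expect_equal(unname(pfm["-", 2]), 1 / 3)
  expect_equal(unname(attr(pfm, "occupancy")), c(1, 2 / 3, 1 / 3))
  classes <- attr(pfm, "residue_classes")
  expect_setequal(unlist(classes), rownames(pfm)[1:20])
  expect_error(position_frequency_matrix(c("AB", "A")), "ragged")
  # stack width of a half-gap column is one half
  half <- position_frequency_matrix(c(a = "Q", b = "-"))
  expect_equal(unname(half["Q", 1]), 0.5)
  expect_equal(unname(half["-", 1]), 0.5)
})

test_that("family profiles order families by median peak hour", {
  assignment <- c(a1 = "F1", a2 = "F1", a3 = "F1",
                  b1 = "F2", b2 = "F2", b3 = "F2", s1 = "singleton")
  map <- data.frame(gene_id = c("a1", "a2", "a3", "b1", "b2", "b3", "s1"),
                    peak_hour = c(7, 7, 7, 5, 5, 6, 1))
  props <- data.frame(protein_id = names(assignment),
                      pct_lcr = c(80, 90, 85, 40, 50, 45, 5),
                      pct_idr = c(70, 75, 72, 30, 35, 32, 0))
  prof <- family_profile(assignment, map, props)
  expect_identical(prof$family, c("F2", "F1"))
  expect_equal(prof$median_peak_hour, c(5, 7))
  expect_equal(prof$mean_pct_lcr, c(45, 85))
  expect_equal(prof$sem_pct_idr[2], sd(c(70, 75, 72)) / sqrt(3))
  ht <- attr(prof, "hour_tables")
  expect_identical(ht$F1[7], 3L)
})

test_that("a planted residue-biased family exceeds the background composition", {
  cfg <- small_cfg(seed = 18)
  sim <- gen_timecourse(cfg)
  prot <- gen_proteome(cfg, sim$truth)
  tr <- sim$truth
  f1 <- tr$gene_id[!is.na(tr$family) & tr$family == "F1"]  # Q-dominant
  bg <- tr$gene_id[is.na(tr$family)][1:50]
  fam_q <- mean_composition(as.character(prot$proteins[f1]))["Q"]
  bg_q <- mean_composition(as.character(prot$proteins[bg]))["Q"]
  expect_gt(fam_q, bg_q + 20)
})
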