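# Tissue enrichment, secretome partition, abundance statistics, cluster
# summaries, lagged tests and network density.

test_that("the enrichment filter applies fold and abundance floors", {
  mat <- rbind(a = c(pharynx = 40, gut = 10, bwm = 8),
               b = c(24, 1, 1),
               c = c(30, 25, 10),
               d = c(100, 10, 90))
  expect_identical(classify_tissue_enriched(mat), "a")
  # b fails the 25-TPM floor, c and d fail the 1.5-fold-vs-max filter;
  # against the mean of the other tissues c and d pass
  expect_identical(classify_tissue_enriched(mat, compare = "mean"),
                   c("a", "c", "d"))
  expect_error(classify_tissue_enriched(mat[, 1, drop = FALSE]), "2 tissues")
  expect_error(classify_tissue_enriched(mat, target = "gland"), "gland")
})

test_that("the enrichment filter equals brute-force enumeration on random matrices", {
  set.seed(7)
  for (rep in 1:5) {
    mat <- matrix(rexp(60 * 5, rate = 1 / 30), nrow = 60,
                  dimnames = list(sprintf("g%02d", 1:60),
                                  c("pharynx", "t2", "t3", "t4", "t5")))
    got <- classify_tissue_enriched(mat)
    want <- rownames(mat)[vapply(seq_len(60), function(i) {
      v <- mat[i, ]
      all(v["pharynx"] > 1.5 * v[-1]) && v["pharynx"] >= 25
    }, TRUE)]
    expect_identical(got, want)
  }
})

test_that("the secretome partition uses an inclusive 0.45 boundary", {
  sc <- c(a = 0.45, b = 0.449, c = 0.9, d = 0.1)
  part <- partition_secretome(names(sc), sc)
  expect_identical(part$secreted, c("a", "c"))
  expect_identical(part$non_secreted, c("b", "d"))
  # the two sets always partition the input
  expect_setequal(c(part$secreted, part$non_secreted), names(sc))
  expect_length(intersect(part$secreted, part$non_secreted), 0)
  expect_warning(p2 <- partition_secretome(c("a", "zz"), sc), "without a score")
  expect_identical(p2$non_secreted, "zz")
})

test_that("bin profiles reproduce the closed-form one-sample t-test", {
  expr <- c(g1 = 10, g2 = 20, g3 = 30)
  hrs <- c(g1 = 2, g2 = 2, g3 = 2)
  prof <- suppressWarnings(bin_abundance_profile(expr, hrs, global_mean = 10))
  # t = 10 / (10/sqrt(3)) = sqrt(3); two-tailed p at df 2 is ~0.2254
  expect_equal(prof$mean[2], 20)
  expect_equal(prof$p[2], 2 * pt(-sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(prof$p[2], 0.225, tolerance = 1e-2)
})

test_that("identical values give every bin p = 1 against the set mean", {
  expr <- stats::setNames(rep(7, 16), sprintf("g%d", 1:16))
  hrs <- stats::setNames(rep(1:8, 2), names(expr))
  prof <- bin_abundance_profile(expr, hrs)
  expect_true(all(prof$mean == 7))
  expect_true(all(prof$p == 1))
})

test_that("bin means recombine to the global mean of the set", {
  set.seed(3)
  expr <- stats::setNames(rexp(200, 1 / 50), sprintf("g%03d", 1:200))
  hrs <- stats::setNames(sample(1:8, 200, TRUE), names(expr))
  prof <- suppressWarnings(bin_abundance_profile(expr, hrs))
  recombined <- sum(prof$mean * prof$n, na.rm = TRUE) / sum(prof$n)
  expect_equal(recombined, attr(prof, "global_mean"), tolerance = 1e-9)
})

test_that("cluster summaries follow the average and max-average rules", {
  mat <- cbind(c1 = c(g1 = 2, g2 = 10), c2 = c(4, 2), c3 = c(100, 100))
  grouping <- list(
    mc = list(clusters = c("c1", "c2"), mode = "average"),
    arc = list(clusters = "c3", mode = "max-average"))
  out <- cluster_summary(mat, grouping)
  expect_equal(out[, "mc"], c(g1 = 3, g2 = 6))
  expect_equal(out[, "arc"], c(g1 = 100, g2 = 100))
  # max-average picks the single best cluster over the gene set, once
  grouping2 <- list(x = list(clusters = c("c1", "c2", "c3"),
                             mode = "max-average"))
  out2 <- cluster_summary(mat, grouping2)
  expect_equal(unname(out2[, "x"]), unname(mat[, "c3"]))
  # average mode is invariant to cluster order
  g3 <- list(mc = list(clusters = c("c2", "c1"), mode = "average"))
  expect_equal(cluster_summary(mat, g3)[, "mc"], out[, "mc"])
  expect_error(cluster_summary(mat, list(a = list(clusters = "zz",
                                                  mode = "average"))),
               "unknown")
  expect_error(cluster_summary(mat, list(
    a = list(clusters = "c1", mode = "average"),
    b = list(clusters = "c1", mode = "average"))), "more than one")
})

test_that("the lagged test flags strong two-hour increases only", {
  set.seed(9)
  vals <- c(rnorm(20, 10), rnorm(20, 100, 1))
  bins <- c(rep(4, 20), rep(6, 20))
  out <- suppressWarnings(lagged_bin_test(vals, bins))
  expect_true(out$flagged[6])
  expect_false(any(out$flagged[c(1, 2)]))
  expect_true(all(is.na(out$p[1:2])))
  # identical bins are never flagged
  vals2 <- rep(5, 80); bins2 <- rep(1:8, each = 10)
  out2 <- lagged_bin_test(vals2, bins2)
  expect_false(any(out2$flagged))
})

test_that("network density counts unique in-set edges per node", {
  nodes <- sprintf("p%02d", 1:20)
  set.seed(1)
  edges <- do.call(rbind, lapply(1:36, function(i) {
    pair <- sample(nodes, 2)
    data.frame(from = pair[1], to = pair[2])
  }))
  # de-duplicate to exactly 36 unique undirected pairs
  while (TRUE) {
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (!anyDuplicated(key)) break
    pair <- sample(nodes, 2)
    edges[which(duplicated(key))[1], ] <- pair
  }
  expect_equal(network_density(nodes, edges)$density, 1.8)
  expect_equal(network_density(nodes, edges[0, ])$density, 0)
  k4 <- t(combn(c("a", "b", "c", "d"), 2))
  expect_equal(network_density(c("a", "b", "c", "d"), k4)$density, 1.5)
  expect_warning(network_density(c("a", "b"), data.frame("a", "zz")),
                 "dropped")
  expect_error(network_density(character(0), k4), "empty")
})

test_that("secretome strata are disjoint, exhaustive and correctly fractioned", {
  cfg <- small_cfg(seed = 13)
  sim <- gen_timecourse(cfg)
  prot <- gen_proteome(cfg, sim$truth)
  scores <- stats::setNames(prot$signalp$signalp_score,
                            prot$signalp$protein_id)
  fits <- fit_gene_phases(sim$expr)
  enr <- sim$truth$gene_id[!is.na(sim$truth$tissue)]
  map <- build_map_table(fits, enriched_genes = enr,
                         signalp_scores = scores)
  st <- summarize_secretome_strata(map, sim$truth$gene_id, scores)
  expect_identical(sum(st$n), cfg$n_genes)
  expect_equal(st$pct_secreted, 100 * st$n_secreted / st$n)
  # planted fractions recovered within binomial noise
  expect_equal(st$pct_secreted[1], 100 * cfg$frac_secreted, tolerance = 0.2)
  expect_equal(st$pct_secreted[3], 100 * cfg$frac_secreted_nonosc,
               tolerance = 0.2)
})
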