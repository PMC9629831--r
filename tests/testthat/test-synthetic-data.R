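# Synthetic-data generator: planted truth, determinism, construction
# guarantees.

test_that("configuration validation names the offending field", {
  expect_error(sim_config(frac_oscillating = 1.2), "frac_oscillating")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(molt_hour = 9), "molt_hour")
  expect_error(sim_config(n_timepoints = 4), "n_timepoints")
  expect_error(sim_config(family_sizes = c(5, 4, 2), n_families = 3),
               "family_sizes")
  expect_error(sim_config(family_sizes = c(5, 4), n_families = 3),
               "family_sizes")
})

test_that("a noise-free planted cosine peaks at phase/360 x period", {
  cfg <- small_cfg(noise_sd = 0)
  sim <- gen_timecourse(cfg)
  tr <- sim$truth
  g <- tr$gene_id[tr$oscillating][1]
  phase <- tr$phase_deg[tr$gene_id == g]
  # dense-grid argmax of the fitted-model curve equals the planted peak
  y <- sim$expr[g, ]
  fit <- fit_phase(y, 0:15, 8)
  grid <- seq(0, 8, by = 1e-4)
  curve <- cos(2 * pi * (grid - fit$phase_deg / 360 * 8) / 8)
  expect_equal(grid[which.max(curve)], phase / 360 * 8, tolerance = 1e-3)
})

test_that("frac_oscillating = 0 plants no oscillating genes", {
  cfg <- small_cfg(frac_oscillating = 0, n_families = 0,
                   family_sizes = integer(0))
  sim <- gen_timecourse(cfg)
  expect_false(any(sim$truth$oscillating))
  expect_true(all(is.na(sim$truth$phase_deg)))
  # families need secreted pharynx-enriched hosts; without oscillators the
  # generator refuses to plant them
  cfg2 <- small_cfg(frac_oscillating = 0)
  expect_error(gen_timecourse(cfg2), "family_sizes")
})

test_that("the same seed reproduces every output bit-for-bit", {
  cfg <- small_cfg(seed = 11)
  a <- gen_timecourse(cfg); b <- gen_timecourse(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  ta <- gen_tissue_matrix(cfg, a$truth); tb <- gen_tissue_matrix(cfg, b$truth)
  expect_identical(ta, tb)
  pa <- gen_proteome(cfg, a$truth); pb <- gen_proteome(cfg, b$truth)
  expect_identical(as.character(pa$proteins), as.character(pb$proteins))
  expect_identical(pa$signalp, pb$signalp)
})

test_that("tissue columns are normalised to one million", {
  cfg <- small_cfg(seed = 2)
  sim <- gen_timecourse(cfg)
  mat <- gen_tissue_matrix(cfg, sim$truth)
  expect_equal(unname(colSums(mat)), rep(1e6, length(cfg$tissues)),
               tolerance = 1e-9)
  expect_true(all(mat >= 0))
})

test_that("without planted enrichment no gene reaches a 1.5-fold tissue bias", {
  cfg <- small_cfg(seed = 5, frac_enriched = 0, n_families = 0,
                   family_sizes = integer(0))
  sim <- gen_timecourse(cfg)
  truth <- sim$truth
  mat <- gen_tissue_matrix(cfg, truth)
  folds <- apply(mat, 1, function(v) max(v) / max(sort(v, TRUE)[2], 1e-12))
  expect_true(all(folds < 1.5))
})

test_that("planted pharynx genes sit enrich_fold above the other tissues", {
  # the fold is planted on the normalised scale: the target column carries
  # the extra enrichment and molt-wave mass, and the generator pre-scales
  # the planted values so the ratio survives column normalisation
  cfg <- small_cfg(seed = 3, tissue_noise = 0)
  sim <- gen_timecourse(cfg)
  mat <- gen_tissue_matrix(cfg, sim$truth)
  tr <- sim$truth
  enr <- !is.na(tr$tissue) & !(tr$secreted & tr$oscillating &
                                 !is.na(tr$peak_bin) &
                                 tr$peak_bin == cfg$molt_hour)
  ratio <- mat[enr, "pharynx"] / apply(mat[enr, -1, drop = FALSE], 1, max)
  expect_equal(unname(ratio), rep(cfg$enrich_fold, sum(enr)),
               tolerance = 1e-6)
})

test_that("zero mutation rate makes family members identical after trimming", {
  cfg <- small_cfg(seed = 4, family_mutation_rate = 0)
  sim <- gen_timecourse(cfg)
  prot <- gen_proteome(cfg, sim$truth)
  tr <- sim$truth
  for (f in unique(na.omit(tr$family))) {
    ids <- tr$gene_id[!is.na(tr$family) & tr$family == f]
    mature <- trim_signal_peptide(
      stats::setNames(as.character(prot$proteins[ids]), ids))
    expect_length(unique(unname(mature)), 1)
  }
})

test_that("emitted signal-peptide scores agree exactly with planted secretion", {
  cfg <- small_cfg(seed = 6)
  sim <- gen_timecourse(cfg)
  prot <- gen_proteome(cfg, sim$truth)
  expect_identical(prot$signalp$signalp_score >= 0.45, sim$truth$secreted)
})

test_that("planted low-complexity tracts are recovered by the SEG oracle", {
  cfg <- small_cfg(seed = 8)
  sim <- gen_timecourse(cfg)
  prot <- gen_proteome(cfg, sim$truth)
  tracts <- prot$lc_tracts[1:2, ]
  for (k in seq_len(nrow(tracts))) {
    s <- as.character(prot$proteins[[tracts$protein_id[k]]])
    segs <- seg_oracle(s)
    overlap <- any(segs$start < tracts$end[k] & segs$end > tracts$start[k])
    expect_true(overlap)
  }
})

test_that("disorder tracks match protein lengths and planted tracts", {
  cfg <- small_cfg(seed = 9)
  sim <- gen_timecourse(cfg)
  prot <- gen_proteome(cfg, sim$truth)
  lens <- Biostrings::width(prot$proteins)
  expect_identical(unname(lengths(prot$disorder)), as.integer(lens))
  fam <- sim$truth$gene_id[!is.na(sim$truth$family)][1]
  idr <- call_idrs(prot$disorder[[fam]])
  expect_gt(idr$pct_idr, 50)
})
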