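# Pipeline orchestration: simulate -> map -> enrich -> properties ->
# families -> report.

#' Secretome signal-peptide fractions across map strata
#'
#' Splits the gene universe into three disjoint, exhaustive strata —
#' tissue-enriched oscillating genes, the remaining oscillating genes and
#' the non-oscillating rest of the genome — and reports the signal-peptide
#' fraction of each.
#'
#' @param map a `moltmap_map` table (supplies the oscillating set and the
#'   tissue_class column).
#' @param genome_genes character vector of every gene id in the genome
#'   universe.
#' @param signalp_scores named numeric vector of signal-peptide scores.
#' @param sp_cutoff score cutoff (default 0.45, inclusive).
#' @return data.frame with stratum, n, n_secreted, pct_secreted.
#' @export
summarize_secretome_strata <- function(map, genome_genes, signalp_scores,
                                       sp_cutoff = 0.45) {
  if (anyDuplicated(genome_genes))
    stopf("summarize_secretome_strata: duplicated gene ids in the genome list")
  if (!all(map$gene_id %in% genome_genes))
    stopf("summarize_secretome_strata: map genes missing from the genome list")
  enriched_osc <- map$gene_id[map$tissue_class != "non-specific"]
  osc_rest <- setdiff(map$gene_id, enriched_osc)
  non_osc <- setdiff(genome_genes, map$gene_id)
  strata <- list(enriched_oscillating = enriched_osc,
                 other_oscillating = osc_rest,
                 non_oscillating = non_osc)
  if (any(vapply(strata, length, 1L) == 0L))
    stopf("summarize_secretome_strata: empty stratum")
  rows <- lapply(names(strata), function(s) {
    part <- partition_secretome(strata[[s]], signalp_scores, sp_cutoff)
    n <- length(strata[[s]])
    data.frame(stratum = s, n = n, n_secreted = length(part$secreted),
               pct_secreted = 100 * length(part$secreted) / n)
  })
  do.call(rbind, rows)
}

# SEG + IDR property table over a whole proteome
build_property_table <- function(proteins, disorder = NULL) {
  seqs <- as.character(proteins)
  rows <- lapply(names(seqs), function(id) {
    segs <- suppressWarnings(seg_low_complexity(seqs[[id]]))
    pidr <- NA_real_
    if (!is.null(disorder) && !is.null(disorder[[id]]))
      pidr <- call_idrs(disorder[[id]])$pct_idr
    data.frame(protein_id = id,
               length = nchar(seqs[[id]]),
               pct_lcr = pct_lcr(seqs[[id]], segs),
               pct_idr = pidr,
               n_lcr_segments = nrow(segs))
  })
  do.call(rbind, rows)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates a synthetic dataset from a [sim_config()], then performs the
#' complete analysis: phase fitting and oscillation calls, map assembly,
#' molt overlay and peak molting hour, pharynx enrichment and secretome
#' classification, secretome strata fractions, the per-bin transcript
#' abundance profile of the secreted pharynx set (against the map-wide
#' global mean), SEG/IDR property quantification, group property
#' enrichment, the transcript-weighted low-complexity wave, and
#' low-complexity family discovery with consensus frequency matrices.
#' Deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @param fold,min_tpm tissue-enrichment thresholds.
#' @param sp_cutoff signal-peptide score cutoff.
#' @param identity_threshold,min_family_size family clustering thresholds.
#' @param lc_pct_min percent-LCR floor a secreted pharynx protein must
#'   reach to enter family discovery (proxy for the domain-less
#'   low-complexity set).
#' @param out_dir optional directory; when supplied, all report tables are
#'   written there via [write_report()].
#' @return A `moltmap_report` list (map, molt overlay and peak hour,
#'   enrichment and strata tables, bin profile, property table, property
#'   enrichment, weighted wave, family results, truth, provenance).
#' @export
run_pipeline <- function(cfg,
                         fold = 1.5, min_tpm = 25, sp_cutoff = 0.45,
                         identity_threshold = 55, min_family_size = 3L,
                         lc_pct_min = 25, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- gen_timecourse(cfg)
  tissue <- gen_tissue_matrix(cfg, sim$truth)
  proteome <- gen_proteome(cfg, sim$truth)
  scores <- stats::setNames(proteome$signalp$signalp_score,
                            proteome$signalp$protein_id)

  fits <- fit_gene_phases(sim$expr, period = cfg$period_hours)
  enriched <- classify_tissue_enriched(tissue, target = cfg$tissues[1L],
                                       fold = fold, min_tpm = min_tpm)
  molt_genes <- sim$truth$gene_id[sim$truth$molt]
  map <- build_map_table(fits, molt_genes = molt_genes,
                         enriched_genes = enriched,
                         signalp_scores = scores,
                         tissue = cfg$tissues[1L], sp_cutoff = sp_cutoff)
  overlay <- suppressWarnings(overlay_molt(map, molt_genes))
  molt_hour <- peak_molt_hour(overlay)

  strata <- summarize_secretome_strata(map, sim$truth$gene_id, scores,
                                       sp_cutoff)
  pharynx_tpm <- stats::setNames(tissue[, cfg$tissues[1L]],
                                 rownames(tissue))
  hours <- stats::setNames(map$peak_hour, map$gene_id)
  global_mean <- mean(pharynx_tpm[map$gene_id])
  sec_enr <- map$gene_id[map$secreted & map$tissue_class != "non-specific"]
  bin_profile <- suppressWarnings(
    bin_abundance_profile(pharynx_tpm, hours, gene_set = sec_enr,
                          global_mean = global_mean))

  properties <- build_property_table(proteome$proteins, proteome$disorder)
  lcr_vals <- stats::setNames(properties$pct_lcr, properties$protein_id)
  groups <- list(secreted_pharynx = sec_enr,
                 other_map_genes = setdiff(map$gene_id, sec_enr))
  prop_enrichment <- suppressWarnings(property_enrichment(groups, lcr_vals))
  wave <- suppressWarnings(
    weighted_property_profile(pharynx_tpm[map$gene_id],
                              lcr_vals[map$gene_id], hours))

  lc_set <- sec_enr[lcr_vals[sec_enr] >= lc_pct_min]
  families <- NULL
  if (length(lc_set) >= 2L) {
    mature <- trim_signal_peptide(
      stats::setNames(as.character(proteome$proteins[lc_set]), lc_set))
    im <- build_identity_matrix(mature)
    fam <- cluster_families(im, identity_threshold, min_family_size)
    pfms <- lapply(fam$families, function(members)
      position_frequency_matrix(center_star_msa(mature[members])))
    profile <- suppressWarnings(
      family_profile(fam$assignment, map, properties))
    families <- list(identity_matrix = im, assignment = fam$assignment,
                     families = fam$families, pfms = pfms,
                     profile = profile)
  }

  report <- structure(list(
    map = map,
    molt_overlay = overlay,
    molt_hour = molt_hour,
    enriched_genes = enriched,
    strata = strata,
    bin_profile = bin_profile,
    global_mean_tpm = global_mean,
    properties = properties,
    property_enrichment = prop_enrichment,
    lcr_wave = wave,
    families = families,
    truth = sim$truth,
    provenance = list(config = unclass(cfg),
                      thresholds = list(fold = fold, min_tpm = min_tpm,
                                        sp_cutoff = sp_cutoff,
                                        identity_threshold = identity_threshold,
                                        min_family_size = min_family_size,
                                        lc_pct_min = lc_pct_min),
                      package_version = as.character(
                        utils::packageVersion("moltmap")))),
    class = "moltmap_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Map summary statistics from a deposited master table (pass-through)
#'
#' Consumes a master table that already carries per-gene phases and
#' annotations — one row per gene of the genome universe, with columns
#' `gene_id`, `oscillating` (logical), `phase_deg` (degrees, oscillating
#' genes), `pharynx_enriched` (logical), `signalp_score`, and optionally
#' `domainless` (logical) and `pharynx_tpm` — and recomputes the map
#' summary statistics from it: oscillating and enriched counts, secretome
#' strata fractions, the domain-less secreted count and the global mean
#' transcript number.
#'
#' @param master data.frame as described above.
#' @param sp_cutoff signal-peptide cutoff (default 0.45, inclusive).
#' @return List with the map table and a `stats` list.
#' @export
report_from_master <- function(master, sp_cutoff = 0.45) {
  need <- c("gene_id", "oscillating", "phase_deg", "pharynx_enriched",
            "signalp_score")
  miss <- setdiff(need, names(master))
  if (length(miss) > 0L)
    stopf("report_from_master: missing column(s) %s",
          paste(miss, collapse = ", "))
  scores <- stats::setNames(master$signalp_score, master$gene_id)
  enriched <- master$gene_id[master$pharynx_enriched & master$oscillating]
  fits <- data.frame(gene_id = master$gene_id,
                     phase_deg = master$phase_deg,
                     oscillating = master$oscillating)
  map <- build_map_table(fits, enriched_genes = enriched,
                         signalp_scores = scores, sp_cutoff = sp_cutoff)
  strata <- summarize_secretome_strata(map, master$gene_id, scores,
                                       sp_cutoff)
  stats_out <- list(
    n_oscillating = nrow(map),
    n_pharynx_enriched = length(enriched),
    n_secreted_enriched = strata$n_secreted[1L],
    pct_secreted_enriched = strata$pct_secreted[1L],
    pct_secreted_other_oscillating = strata$pct_secreted[2L],
    pct_secreted_non_oscillating = strata$pct_secreted[3L])
  if ("domainless" %in% names(master)) {
    sec_enr <- map$gene_id[map$secreted & map$tissue_class != "non-specific"]
    stats_out$n_domainless_secreted <-
      sum(master$domainless[match(sec_enr, master$gene_id)], na.rm = TRUE)
  }
  if ("pharynx_tpm" %in% names(master)) {
    stats_out$global_mean_tpm <-
      mean(master$pharynx_tpm[match(map$gene_id, master$gene_id)],
           na.rm = TRUE)
    stats_out$n_pharynx_enriched_all <-
      sum(master$pharynx_enriched, na.rm = TRUE)
  }
  list(map = map, strata = strata, stats = stats_out)
}

#' Write a pipeline report to a directory of TSV tables
#'
#' Every table is written deterministically ordered with its thresholds in
#' `#` header comments; the provenance block (config, thresholds, package
#' version) goes to `provenance.json`.
#'
#' @param report a `moltmap_report` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "moltmap_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  th <- report$provenance$thresholds
  hdr <- sprintf("%s=%s", names(th), unlist(th))
  write_tsv(as.data.frame(report$map), file.path(dir, "map.tsv"), hdr)
  write_tsv(data.frame(bin = 1:8, molt_overlap = report$molt_overlay),
            file.path(dir, "molt_overlay.tsv"),
            c(hdr, sprintf("peak_molt_hour=%d", report$molt_hour)))
  write_tsv(report$strata, file.path(dir, "secretome_strata.tsv"), hdr)
  write_tsv(report$bin_profile, file.path(dir, "bin_profile.tsv"),
            c(hdr, sprintf("global_mean_tpm=%.4f", report$global_mean_tpm)))
  write_tsv(report$properties, file.path(dir, "properties.tsv"), hdr)
  write_tsv(report$property_enrichment,
            file.path(dir, "property_enrichment.tsv"), hdr)
  write_tsv(report$lcr_wave, file.path(dir, "lcr_wave.tsv"), hdr)
  if (!is.null(report$families)) {
    asg <- report$families$assignment
    write_tsv(data.frame(protein_id = names(asg), family = unname(asg)),
              file.path(dir, "families.tsv"), hdr)
    write_tsv(report$families$profile,
              file.path(dir, "family_profile.tsv"), hdr)
    for (f in names(report$families$pfms)) {
      pfm <- report$families$pfms[[f]]
      write_tsv(data.frame(residue = rownames(pfm), pfm,
                           check.names = FALSE),
                file.path(dir, sprintf("pfm_%s.tsv", f)), hdr)
    }
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.moltmap_report <- function(x, ...) {
  cat("moltmap pipeline report\n")
  cat(sprintf("  oscillating genes on the map : %d\n", nrow(x$map)))
  cat(sprintf("  peak molting hour            : %d\n", x$molt_hour))
  cat(sprintf("  pharynx-enriched (oscillating): %d\n",
              sum(x$map$tissue_class != "non-specific")))
  cat(sprintf("  secreted of those            : %d (%.0f%%)\n",
              x$strata$n_secreted[1L], x$strata$pct_secreted[1L]))
  if (!is.null(x$families))
    cat(sprintf("  low-complexity families      : %d\n",
                length(x$families$families)))
  invisible(x)
}
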