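#' Configuration for the synthetic molting-cycle data generator
#'
#' Bundles every tunable of the synthetic-data module into a validated list.
#' The defaults describe the study conditions the pipeline is designed
#' around: a 16-hour time course sampled hourly across two 8-hour molting
#' cycles, roughly 13% of the genome oscillating, a molt-upregulated subset
#' concentrated at hour 6, pharynx enrichment planted at 4-fold, a 62%
#' secreted fraction among the pharynx-enriched oscillators (39% among the
#' remaining oscillators and 17% among non-oscillating genes), a 30-fold
#' transcript-abundance wave for secreted pharynx genes at the molt hour,
#' and six low-complexity protein families with distinct residue biases.
#'
#' @param n_genes number of genes to simulate.
#' @param frac_oscillating fraction of genes given a cosine oscillation.
#' @param period_hours oscillation period in hours.
#' @param n_timepoints number of hourly samples; must cover at least one
#'   full period.
#' @param amplitude_range length-2 range (log2 units) from which planted
#'   amplitudes are drawn uniformly.
#' @param noise_sd Gaussian noise standard deviation (log2 units) added to
#'   every timepoint.
#' @param baseline_range length-2 range (log2 units) of per-gene baselines.
#' @param molt_hour hourly bin (1..8) at which the planted molt-upregulated
#'   subset is concentrated.
#' @param molt_fraction fraction of oscillating genes flagged
#'   molt-upregulated.
#' @param tissues character vector of tissue names; the first must be the
#'   enrichment target (pharynx).
#' @param enrich_fold planted fold enrichment of pharynx genes over every
#'   other tissue.
#' @param frac_enriched fraction of oscillating genes planted as
#'   pharynx-enriched.
#' @param tissue_noise half-width of the multiplicative uniform jitter
#'   applied to tissue expression values (0 disables it).
#' @param mean_tpm median transcripts-per-million of the lognormal baseline
#'   abundance distribution.
#' @param abundance_fold fold increase over the oscillating-set global mean
#'   planted into the pharynx abundance of secreted pharynx-enriched genes
#'   peaking at `molt_hour`.
#' @param frac_secreted secreted fraction among pharynx-enriched
#'   oscillating genes.
#' @param frac_secreted_osc secreted fraction among the remaining
#'   oscillating genes.
#' @param frac_secreted_nonosc secreted fraction among non-oscillating
#'   genes.
#' @param n_families number of planted low-complexity families (at most 6,
#'   one per distinct dominant residue).
#' @param family_sizes integer vector (length `n_families`) of member
#'   counts; every entry must be at least 3.
#' @param family_mutation_rate per-residue substitution probability applied
#'   to each family member relative to its family consensus.
#' @param seed integer seed; fixes every generator output bit-for-bit.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 4000,
                       frac_oscillating = 0.134,
                       period_hours = 8,
                       n_timepoints = 16,
                       amplitude_range = c(0.5, 2),
                       noise_sd = 0.25,
                       baseline_range = c(4, 10),
                       molt_hour = 6,
                       molt_fraction = 0.22,
                       tissues = c("pharynx", "hypodermis", "BWM", "glia",
                                   "gonad", "intestine", "neurons"),
                       enrich_fold = 4,
                       frac_enriched = 0.135,
                       tissue_noise = 0.05,
                       mean_tpm = 30,
                       abundance_fold = 30,
                       frac_secreted = 0.62,
                       frac_secreted_osc = 0.39,
                       frac_secreted_nonosc = 0.17,
                       n_families = 6,
                       family_sizes = c(7, 6, 5, 5, 5, 5),
                       family_mutation_rate = 0.15,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              frac_oscillating = frac_oscillating,
              period_hours = period_hours,
              n_timepoints = as.integer(n_timepoints),
              amplitude_range = amplitude_range,
              noise_sd = noise_sd,
              baseline_range = baseline_range,
              molt_hour = as.integer(molt_hour),
              molt_fraction = molt_fraction,
              tissues = tissues,
              enrich_fold = enrich_fold,
              frac_enriched = frac_enriched,
              tissue_noise = tissue_noise,
              mean_tpm = mean_tpm,
              abundance_fold = abundance_fold,
              frac_secreted = frac_secreted,
              frac_secreted_osc = frac_secreted_osc,
              frac_secreted_nonosc = frac_secreted_nonosc,
              n_families = as.integer(n_families),
              family_sizes = as.integer(family_sizes),
              family_mutation_rate = family_mutation_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("frac_oscillating", "molt_fraction", "frac_enriched",
                   "frac_secreted", "frac_secreted_osc",
                   "frac_secreted_nonosc", "family_mutation_rate",
                   "tissue_noise")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stopf("invalid configuration: %s must be a fraction in [0, 1]", f)
  }
  if (cfg$n_genes < 1L)
    stopf("invalid configuration: n_genes must be positive")
  if (!is.numeric(cfg$period_hours) || cfg$period_hours <= 0)
    stopf("invalid configuration: period_hours must be positive")
  if (cfg$n_timepoints < cfg$period_hours)
    stopf("invalid configuration: n_timepoints must cover one full period_hours")
  if (length(cfg$amplitude_range) != 2L || any(cfg$amplitude_range <= 0) ||
      diff(cfg$amplitude_range) < 0)
    stopf("invalid configuration: amplitude_range must be an ascending positive pair")
  if (length(cfg$baseline_range) != 2L || diff(cfg$baseline_range) < 0)
    stopf("invalid configuration: baseline_range must be an ascending pair")
  if (cfg$noise_sd < 0)
    stopf("invalid configuration: noise_sd must be non-negative")
  if (cfg$molt_hour < 1L || cfg$molt_hour > 8L)
    stopf("invalid configuration: molt_hour must be a bin in 1..8")
  if (length(cfg$tissues) < 2L || anyDuplicated(cfg$tissues))
    stopf("invalid configuration: tissues must be >= 2 unique names")
  if (cfg$enrich_fold <= 1)
    stopf("invalid configuration: enrich_fold must exceed 1")
  if (cfg$mean_tpm <= 0)
    stopf("invalid configuration: mean_tpm must be positive")
  if (cfg$abundance_fold < 1)
    stopf("invalid configuration: abundance_fold must be at least 1")
  if (cfg$n_families < 0L || cfg$n_families > 6L)
    stopf("invalid configuration: n_families must be in 0..6")
  if (length(cfg$family_sizes) != cfg$n_families)
    stopf("invalid configuration: family_sizes must have length n_families")
  if (any(cfg$family_sizes < 3L))
    stopf("invalid configuration: family_sizes entries must be at least 3")
  if (is.na(cfg$seed))
    stopf("invalid configuration: seed must be an integer")
  invisible(cfg)
}
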