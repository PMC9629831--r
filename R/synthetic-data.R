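# Synthetic-data generator: every pipeline input with planted ground truth.
#
# The generator emulates the shape of the source datasets the pipeline is
# designed for: a 16-hour hourly expression series with cosine-shaped
# oscillations on the log2 scale, tissue-level TPM summaries with planted
# pharynx enrichment, signal-peptide scores around the 0.45 convention, and
# a proteome carrying low-complexity families with mutational divergence.

# Planted truth assignment. Called once at the top of gen_timecourse so a
# single seed fixes the whole truth table; downstream generators consume
# the truth rather than re-drawing labels.
gen_truth <- function(cfg) {
  # sample() on a length-one integer would sample 1:x; avoid that trap
  draw <- function(pool, size, prob = NULL)
    pool[sample.int(length(pool), size, prob = prob)]
  n <- cfg$n_genes
  ids <- sprintf("g%06d", seq_len(n))
  n_osc <- round(cfg$frac_oscillating * n)
  osc_idx <- sort(sample.int(n, n_osc))
  oscillating <- seq_len(n) %in% osc_idx

  phase <- rep(NA_real_, n)
  phase[osc_idx] <- stats::runif(n_osc, 0, 360)
  bin <- rep(NA_integer_, n)
  bin[osc_idx] <- floor(phase[osc_idx] / 45) + 1L

  # molt-upregulated subset: drawn from oscillating genes with weights
  # concentrated on the molt bin (and, weakly, its circular neighbours)
  molt <- rep(FALSE, n)
  if (n_osc > 0L && cfg$molt_fraction > 0) {
    d <- pmin(abs(bin[osc_idx] - cfg$molt_hour),
              8L - abs(bin[osc_idx] - cfg$molt_hour))
    w <- ifelse(d == 0L, 1, ifelse(d == 1L, 0.25, 0.02))
    m <- min(round(cfg$molt_fraction * n_osc), n_osc)
    if (m > 0L) molt[draw(osc_idx, m, prob = w)] <- TRUE
  }

  tissue <- rep(NA_character_, n)
  n_enr <- min(round(cfg$frac_enriched * n_osc), n_osc)
  if (n_enr > 0L) tissue[draw(osc_idx, n_enr)] <- cfg$tissues[1L]

  enr <- !is.na(tissue)
  p_sec <- ifelse(oscillating & enr, cfg$frac_secreted,
                  ifelse(oscillating, cfg$frac_secreted_osc,
                         cfg$frac_secreted_nonosc))
  secreted <- stats::runif(n) < p_sec

  family <- rep(NA_character_, n)
  pool <- which(secreted & enr)
  need <- sum(cfg$family_sizes)
  if (need > length(pool))
    stopf(paste0("invalid configuration: family_sizes sum (%d) exceeds the ",
                 "number of secreted pharynx-enriched genes (%d)"),
          need, length(pool))
  if (need > 0L) {
    members <- draw(pool, need)
    family[members] <- rep(sprintf("F%d", seq_len(cfg$n_families)),
                           times = cfg$family_sizes)
  }

  data.frame(gene_id = ids,
             oscillating = oscillating,
             phase_deg = phase,
             peak_bin = bin,
             molt = molt,
             tissue = tissue,
             secreted = secreted,
             family = family,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic log2 expression time course with planted truth
#'
#' Oscillating genes follow `baseline + A * cos(2 * pi * (t - t_peak) /
#' period)` plus Gaussian noise, with `t_peak = phase / 360 * period` and
#' phases uniform on \[0, 360). Non-oscillating genes are baseline plus
#' noise. The returned truth table records every planted label (phase,
#' hourly bin, molt flag, enriched tissue, secreted flag, family label) and
#' is the reference for all downstream recovery tests.
#'
#' @param cfg a [sim_config()] object.
#' @return A list with `expr` (gene x timepoint matrix, columns `h0..`) and
#'   `truth` (one row per gene).
#' @export
gen_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  truth <- gen_truth(cfg)
  n <- cfg$n_genes
  tpts <- seq_len(cfg$n_timepoints) - 1
  baseline <- stats::runif(n, cfg$baseline_range[1L], cfg$baseline_range[2L])
  amp <- rep(0, n)
  osc <- truth$oscillating
  amp[osc] <- stats::runif(sum(osc), cfg$amplitude_range[1L],
                           cfg$amplitude_range[2L])
  t_peak <- ifelse(osc, truth$phase_deg / 360 * cfg$period_hours, 0)

  signal <- outer(seq_len(n), tpts, function(i, t)
    baseline[i] + amp[i] * cos(2 * pi * (t - t_peak[i]) / cfg$period_hours))
  expr <- signal + matrix(stats::rnorm(n * length(tpts), sd = cfg$noise_sd),
                          nrow = n)
  dimnames(expr) <- list(truth$gene_id, sprintf("h%d", tpts))
  truth$amplitude <- amp
  truth$baseline <- baseline
  message(sprintf("gen_timecourse: %d genes (%d oscillating), seed %d",
                  n, sum(osc), cfg$seed))
  list(expr = expr, truth = truth)
}

#' Generate a tissue x gene TPM matrix with planted pharynx enrichment
#'
#' Every gene draws a lognormal baseline abundance shared across tissues
#' (with a small multiplicative jitter); genes planted as pharynx-enriched
#' have their pharynx value raised `enrich_fold`-fold above the other
#' tissues and clear the 25-TPM abundance floor by construction. Secreted
#' pharynx-enriched genes peaking at the molt hour additionally receive a
#' pharynx abundance equal to `abundance_fold` times the resulting global
#' mean over all oscillating genes (solved in closed form), which plants
#' the molt-hour transcript wave. Columns are finally normalised to one
#' million.
#'
#' @param cfg a [sim_config()] object.
#' @param truth truth table from [gen_timecourse()].
#' @param normalize normalise each tissue column to 1e6 (default TRUE).
#' @return Numeric matrix, genes x tissues, TPM units.
#' @export
gen_tissue_matrix <- function(cfg, truth, normalize = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genes
  tis <- cfg$tissues
  target <- tis[1L]
  b <- stats::rlnorm(n, meanlog = log(cfg$mean_tpm), sdlog = 1)
  enr <- !is.na(truth$tissue) & truth$tissue == target
  # floor the baseline of enriched genes so the planted target value
  # always clears the downstream 25-TPM filter with margin
  b[enr] <- pmax(b[enr], 1.5 * 30 / cfg$enrich_fold)

  jit <- function(k) stats::runif(k, 1 - cfg$tissue_noise,
                                  1 + cfg$tissue_noise)
  mat <- vapply(tis, function(ts) b * jit(n), numeric(n))
  dimnames(mat) <- list(truth$gene_id, tis)
  u_enr <- jit(sum(enr))

  boost <- enr & truth$secreted & truth$oscillating &
    !is.na(truth$peak_bin) & truth$peak_bin == cfg$molt_hour
  osc <- truth$oscillating
  k <- sum(boost)
  if (k * cfg$abundance_fold >= sum(osc))
    stopf(paste0("invalid configuration: abundance_fold x boosted genes ",
                 "(%d x %g) must stay below the oscillating gene count (%d)"),
          k, cfg$abundance_fold, sum(osc))

  # The planted pharynx values must survive the per-column normalisation:
  # the target column carries the enrichment and molt-wave mass, so its
  # sum (and hence its normalisation factor) exceeds the other columns'.
  # Pre-scale the planted values by the induced column-sum ratio cc so
  # that, after normalisation, enriched genes sit enrich_fold above the
  # other tissues while molt-bin genes sit abundance_fold above the
  # oscillating-set mean. Both conditions are linear in cc:
  #   gbar = (R_osc + cc*fold*Eb) / (N_osc - k*F)
  #   cc * S_other = R_all + cc*fold*Eb + k*F*gbar
  # which gives the closed form below; an infeasible configuration (the
  # planted mass exceeding what the column can carry) has no solution.
  s_other <- mean(colSums(mat[, setdiff(tis, target), drop = FALSE]))
  n_osc <- sum(osc)
  kF <- k * cfg$abundance_fold
  r_all <- sum(mat[!enr, target])
  r_osc <- sum(mat[osc & !enr, target])
  eb <- sum(b[enr & !boost] * u_enr[!boost[enr]])
  denom <- s_other - cfg$enrich_fold * eb * n_osc / (n_osc - kF)
  if (denom <= 0)
    stopf(paste0("invalid configuration: planted enrichment and ",
                 "abundance_fold mass exceed what column normalisation ",
                 "can carry; lower frac_enriched, enrich_fold or ",
                 "abundance_fold"))
  cc <- (r_all + kF * r_osc / (n_osc - kF)) / denom
  mat[enr, target] <- cc * cfg$enrich_fold * b[enr] * u_enr
  if (k > 0L) {
    gbar <- sum(mat[osc & !boost, target]) / (n_osc - kF)
    mat[boost, target] <- cfg$abundance_fold * gbar
  }

  if (normalize) mat <- sweep(mat, 2L, colSums(mat) / 1e6, "/")
  mat
}

# family-specific residue frequency vectors: one dominant residue per
# family plus two minor residues, mirroring composition-contrast families
family_composition <- function(n_families, rng_secondary = TRUE) {
  dominants <- c("Q", "C", "P", "N", "G", "H")[seq_len(n_families)]
  lapply(dominants, function(d) {
    others <- setdiff(AA20, d)
    sec <- sample(others, 2L)
    w <- stats::setNames(rep(0.21 / 17, 20L), AA20)
    w[d] <- 0.55
    w[sec] <- 0.12
    w / sum(w)
  })
}

mutate_seq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit],
                         function(a) sample(setdiff(AA20, a), 1L), "")
  chars
}

#' Generate a synthetic proteome with planted low-complexity families
#'
#' One protein per gene. Members of each planted family are per-residue
#' mutated copies of a family consensus drawn from a family-specific,
#' strongly biased residue frequency vector (Q-rich, C-rich, ...), so they
#' carry long low-complexity tracts. All other proteins are drawn uniformly
#' over the 20 canonical residues. Secreted proteins are prefixed with a
#' 20-residue hydrophobic leader and receive a signal-peptide score of at
#' least 0.45 in the emitted score table; non-secreted proteins score below
#' 0.45. Disorder tracks are piecewise constant: high inside planted
#' low-complexity tracts (and inside extra disordered runs planted in a
#' tenth of the background proteins), low elsewhere.
#'
#' @param cfg a [sim_config()] object.
#' @param truth truth table from [gen_timecourse()].
#' @return A list with `proteins` (named `Biostrings::AAStringSet`),
#'   `signalp` (data.frame of protein_id, signalp_score), `disorder`
#'   (named list of per-residue probabilities) and `lc_tracts` (data.frame
#'   of planted tract coordinates, 0-based half-open).
#' @export
gen_proteome <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- cfg$n_genes
  comps <- family_composition(cfg$n_families)
  cons_len <- sample(80:160, cfg$n_families, replace = TRUE)
  consensus <- lapply(seq_len(cfg$n_families), function(f)
    sample(AA20, cons_len[f], replace = TRUE, prob = comps[[f]]))

  hydroph <- c("L", "A", "V", "I", "F", "W", "M")
  fam_idx <- match(truth$family, sprintf("F%d", seq_len(cfg$n_families)))
  idr_extra <- !truth$secreted & is.na(truth$family) &
    stats::runif(n) < 0.10

  seqs <- character(n)
  disorder <- vector("list", n)
  tract <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(fam_idx[i])) {
      mature <- mutate_seq(consensus[[fam_idx[i]]], cfg$family_mutation_rate)
      d_mat <- rep(0.9, length(mature))
      lc <- c(0L, length(mature))
    } else {
      len <- sample(150:400, 1L)
      mature <- sample(AA20, len, replace = TRUE)
      d_mat <- rep(0.05, len)
      lc <- NULL
      if (idr_extra[i] && len > 80L) {
        run <- sample(30:80, 1L)
        at <- sample.int(len - run, 1L)
        d_mat[at:(at + run - 1L)] <- 0.9
      }
    }
    if (truth$secreted[i]) {
      leader <- c("M", sample(hydroph, 19L, replace = TRUE))
      seqs[i] <- paste(c(leader, mature), collapse = "")
      disorder[[i]] <- c(rep(0.05, 20L), d_mat)
      if (!is.null(lc)) lc <- lc + 20L
    } else {
      seqs[i] <- paste(mature, collapse = "")
      disorder[[i]] <- d_mat
    }
    if (!is.null(lc))
      tract[[i]] <- data.frame(protein_id = truth$gene_id[i],
                               start = lc[1L], end = lc[2L])
  }

  names(disorder) <- truth$gene_id
  score <- ifelse(truth$secreted,
                  stats::runif(n, 0.50, 0.95),
                  stats::runif(n, 0.00, 0.40))
  proteins <- Biostrings::AAStringSet(stats::setNames(seqs, truth$gene_id))
  message(sprintf("gen_proteome: %d proteins, %d family members, seed %d",
                  n, sum(!is.na(fam_idx)), cfg$seed + 2L))
  list(proteins = proteins,
       signalp = data.frame(protein_id = truth$gene_id,
                            signalp_score = score,
                            stringsAsFactors = FALSE),
       disorder = disorder,
       lc_tracts = do.call(rbind, tract[!vapply(tract, is.null, TRUE)]))
}
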