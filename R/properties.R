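# Disorder, composition and predictor-score aggregation.

#' Call intrinsically disordered regions from a disorder track
#'
#' A residue is disordered when its per-residue disorder probability
#' reaches `prob_threshold`; maximal disordered runs of at least `min_run`
#' residues (the "30 or more contiguous residues" rule) are reported as
#' IDRs.
#'
#' @param disorder_track numeric vector of per-residue probabilities in
#'   \[0, 1].
#' @param prob_threshold disorder call threshold, inclusive (default 0.5).
#' @param min_run minimum IDR length in residues (default 30).
#' @return List with `intervals` (data.frame start, end; 0-based
#'   half-open) and `pct_idr` (percent residues inside IDRs).
#' @export
call_idrs <- function(disorder_track, prob_threshold = 0.5, min_run = 30L) {
  if (length(disorder_track) == 0L)
    stopf("call_idrs: empty disorder track")
  if (any(disorder_track < 0 | disorder_track > 1, na.rm = TRUE))
    stopf("call_idrs: probabilities must lie in [0, 1]")
  dis <- !is.na(disorder_track) & disorder_track >= prob_threshold
  r <- rle(dis)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  intervals <- data.frame(start = starts[keep] - 1L, end = stops[keep])
  list(intervals = intervals,
       pct_idr = 100 * sum(intervals$end - intervals$start) /
         length(disorder_track))
}

#' Mean amino-acid composition of a protein set
#'
#' Per-protein composition percentages averaged across proteins
#' (unweighted), so each protein contributes equally regardless of length;
#' rows sum to 100. A pooled, length-weighted mode is available with
#' `weighted = TRUE`.
#'
#' @param proteins `Biostrings::AAStringSet` or character vector of
#'   canonical sequences.
#' @param weighted pool residues across proteins instead of averaging
#'   per-protein percentages.
#' @return Named numeric vector of 20 percentages summing to 100.
#' @export
mean_composition <- function(proteins, weighted = FALSE) {
  if (length(proteins) == 0L)
    stopf("mean_composition: empty protein set")
  x <- Biostrings::AAStringSet(proteins)
  counts <- Biostrings::letterFrequency(x, letters = AA20)
  if (any(rowSums(counts) != Biostrings::width(x)))
    stopf("mean_composition: non-canonical residues present")
  if (weighted) {
    tot <- colSums(counts)
    return(100 * tot / sum(tot))
  }
  pct <- 100 * counts / rowSums(counts)
  stats::setNames(colMeans(pct), AA20)
}

#' Shift PLAAC scores into a non-negative display range
#'
#' PLAAC reports scores down to -60; adding 60 places all scores on a
#' non-negative scale for charting.
#'
#' @param raw_score numeric raw PLAAC score(s), each at least -60.
#' @return raw_score + 60.
#' @export
adjust_plaac <- function(raw_score) {
  if (any(raw_score < -60, na.rm = TRUE))
    stopf("adjust_plaac: raw score below -60")
  raw_score + 60
}

#' Per-group property means tested against the global mean
#'
#' For each protein group, the mean and SEM of a property together with a
#' two-tailed one-sample Student's t-test against the global mean computed
#' over all proteins carrying the property. Proteins without a value are
#' excluded with a warning; groups smaller than two get p = 1.
#'
#' @param groups named list of protein-id character vectors.
#' @param values named numeric vector of per-protein property values.
#' @return data.frame with group, n, mean, sem, p; the global mean in
#'   `attr(, "global_mean")`.
#' @export
property_enrichment <- function(groups, values) {
  values <- values[!is.na(values)]
  global_mean <- mean(values)
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    x <- values[intersect(ids, names(values))]
    dropped <- length(ids) - length(x)
    if (dropped > 0L)
      warnf("property_enrichment: %d protein(s) in group '%s' lack the property",
            dropped, g)
    n <- length(x)
    if (n < 2L) {
      warnf("property_enrichment: group '%s' has fewer than 2 values; p set to 1", g)
      return(data.frame(group = g, n = n,
                        mean = if (n) mean(x) else NA_real_,
                        sem = NA_real_, p = 1))
    }
    data.frame(group = g, n = n, mean = mean(x),
               sem = stats::sd(x) / sqrt(n),
               p = one_sample_p(x, global_mean))
  })
  out <- do.call(rbind, rows)
  attr(out, "global_mean") <- global_mean
  out
}

#' Transcript-weighted temporal property profile
#'
#' For each gene the transcript abundance is multiplied by the value of a
#' gene-product property (percent LCR, percent IDR, a predictor score,
#' ...), and the products are averaged within each hourly bin. The profile
#' is linear in the transcript counts.
#'
#' @param transcripts named numeric vector of per-gene transcript
#'   abundance.
#' @param property named numeric vector of per-gene property values.
#' @param peak_hours named integer vector of hourly bins.
#' @param n_bins number of bins (default 8).
#' @return data.frame with bin, n and mean (mean of transcript x property
#'   over the genes peaking in that bin; NA for empty bins).
#' @export
weighted_property_profile <- function(transcripts, property, peak_hours,
                                      n_bins = 8L) {
  genes <- intersect(names(transcripts), names(peak_hours))
  have <- genes[genes %in% names(property) & !is.na(property[genes])]
  if (length(have) < length(genes))
    warnf("weighted_property_profile: %d gene(s) without a property value excluded",
          length(genes) - length(have))
  w <- transcripts[have] * property[have]
  hrs <- peak_hours[have]
  out <- data.frame(bin = seq_len(n_bins), n = NA_integer_, mean = NA_real_)
  for (b in seq_len(n_bins)) {
    x <- w[!is.na(hrs) & hrs == b]
    out$n[b] <- length(x)
    out$mean[b] <- if (length(x)) mean(x) else NA_real_
  }
  out
}

#' Remove a predicted signal peptide from a sequence
#'
#' Drops the first `n` residues (default 20); intended for
#' predicted-secreted proteins before alignment, so leader hydrophobicity
#' does not inflate identity.
#'
#' @param seq protein sequence string(s).
#' @param n leader length to remove (default 20).
#' @return Sequence(s) without the leader.
#' @export
trim_signal_peptide <- function(seq, n = 20L) {
  if (any(nchar(seq) <= n))
    stopf("trim_signal_peptide: sequence length must exceed %d", n)
  out <- substring(seq, n + 1L)
  names(out) <- names(seq)
  out
}
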