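# Temporal map: phase fitting, hourly binning, molt overlay.

#' Fit the oscillation phase of a single expression time course
#'
#' Harmonic regression of log2 expression on cosine and sine terms at the
#' molting period. The fitted curve is `baseline + a*cos(wt) + b*sin(wt)`,
#' which peaks at `t_peak = atan2(b, a) / w`; the phase in degrees is
#' `t_peak / period * 360`, so a gene peaking 5 h into an 8-h cycle has
#' phase 225. The oscillation p-value is the F-test of the two harmonic
#' terms against the intercept-only model.
#'
#' @param y numeric log2 expression values.
#' @param times observation times in hours (defaults to hourly from 0).
#' @param period oscillation period in hours.
#' @return List with `phase_deg` in \[0, 360) (NA for a constant series),
#'   `amplitude` (`sqrt(a^2 + b^2)`, log2 units) and `osc_pvalue`.
#' @export
fit_phase <- function(y, times = seq_along(y) - 1, period = 8) {
  if (length(y) < 4L)
    stopf("fit_phase: need at least 4 timepoints, got %d", length(y))
  if (length(times) != length(y))
    stopf("fit_phase: times and y lengths differ")
  if (stats::sd(y) == 0)
    return(list(phase_deg = NA_real_, amplitude = 0, osc_pvalue = 1))
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  fit <- stats::lm.fit(X, y)
  a <- fit$coefficients[2L]
  b <- fit$coefficients[3L]
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  fstat <- ((rss0 - rss1) / 2) / (rss1 / (length(y) - 3L))
  p <- stats::pf(fstat, 2, length(y) - 3L, lower.tail = FALSE)
  if (rss1 == 0) p <- 0
  list(phase_deg = as.numeric((atan2(b, a) * 180 / pi) %% 360),
       amplitude = as.numeric(sqrt(a^2 + b^2)),
       osc_pvalue = as.numeric(p))
}

#' Fit phases for every gene of a time-course matrix
#'
#' Vectorised harmonic regression over all rows of a gene x timepoint
#' matrix, followed by the oscillation call: a gene is called oscillating
#' when its harmonic F-test p-value is below `p_cutoff` (the map's p<0.001
#' convention) and its fitted amplitude reaches `min_amplitude`. The
#' amplitude floor keeps tiny-amplitude genes from being flagged at low
#' noise on a p-value alone.
#'
#' @param expr gene x timepoint matrix; column names like `h0`, `h1`, ...
#'   supply the observation times, otherwise hourly times from 0 are
#'   assumed.
#' @param times optional numeric observation times overriding the column
#'   names.
#' @param period oscillation period in hours.
#' @param p_cutoff oscillation p-value threshold.
#' @param min_amplitude amplitude floor in log2 units.
#' @return data.frame with gene_id, phase_deg, peak_hour, amplitude,
#'   osc_pvalue, oscillating. phase_deg and peak_hour are NA for genes not
#'   called oscillating.
#' @export
fit_gene_phases <- function(expr, times = NULL, period = 8,
                            p_cutoff = 0.001, min_amplitude = 0.25) {
  if (ncol(expr) < 4L)
    stopf("fit_gene_phases: need at least 4 timepoints, got %d", ncol(expr))
  if (is.null(times)) {
    parsed <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", colnames(expr))))
    times <- if (length(parsed) && !anyNA(parsed)) parsed
             else seq_len(ncol(expr)) - 1
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  coef <- solve(crossprod(X), crossprod(X, t(expr)))  # 3 x n
  fitted <- X %*% coef
  rss1 <- colSums((t(expr) - fitted)^2)
  rss0 <- rowSums((expr - rowMeans(expr))^2)
  n_t <- ncol(expr)
  fstat <- ((rss0 - rss1) / 2) / (rss1 / (n_t - 3L))
  p <- stats::pf(fstat, 2, n_t - 3L, lower.tail = FALSE)
  p[rss1 <= .Machine$double.eps * rss0] <- 0
  amplitude <- sqrt(coef[2L, ]^2 + coef[3L, ]^2)
  phase <- (atan2(coef[3L, ], coef[2L, ]) * 180 / pi) %% 360

  constant <- rss0 < 1e-12
  amplitude[constant] <- 0
  p[constant] <- 1
  phase[constant] <- NA_real_

  oscillating <- p < p_cutoff & amplitude >= min_amplitude
  phase[!oscillating] <- NA_real_
  data.frame(gene_id = rownames(expr),
             phase_deg = phase,
             peak_hour = ifelse(oscillating, floor(phase / 45) + 1L,
                                NA_integer_),
             amplitude = amplitude,
             osc_pvalue = p,
             oscillating = oscillating,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Convert a peak phase in degrees to an hourly bin
#'
#' The circle of the 8-hour cycle is partitioned into eight half-open
#' 45-degree bins: bin k covers \[45(k-1), 45k). Hour labels are 1-based,
#' so the molt falls in bin 6 for phases in \[225, 270).
#'
#' @param phase_deg numeric vector of phases in \[0, 360).
#' @return Integer bins in 1..8.
#' @export
phase_to_hour <- function(phase_deg) {
  if (anyNA(phase_deg) || any(phase_deg < 0 | phase_deg >= 360))
    stopf("phase_to_hour: phases must lie in [0, 360)")
  as.integer(floor(phase_deg / 45) + 1L)
}

#' Assemble the spatiotemporal map table
#'
#' Restricts a phase-fit table to genes called oscillating, sorts them by
#' ascending phase (the map's y-axis order: earliest peak first), assigns
#' hourly bins, and overlays the molt, tissue-enrichment and secretome
#' annotations.
#'
#' @param fits data.frame from [fit_gene_phases()] (or a pass-through
#'   table with gene_id, phase_deg and oscillating columns).
#' @param molt_genes optional character vector of molt-upregulated gene
#'   ids.
#' @param enriched_genes optional character vector of tissue-enriched gene
#'   ids.
#' @param signalp_scores optional named numeric vector of signal-peptide
#'   scores.
#' @param tissue label applied to enriched genes (default "pharynx").
#' @param sp_cutoff signal-peptide score cutoff (secreted iff score >=
#'   cutoff).
#' @return data.frame of class `moltmap_map`, sorted by phase, with
#'   per-bin counts in `attr(, "bin_counts")`.
#' @export
build_map_table <- function(fits, molt_genes = NULL, enriched_genes = NULL,
                            signalp_scores = NULL, tissue = "pharynx",
                            sp_cutoff = 0.45) {
  need <- c("gene_id", "phase_deg", "oscillating")
  if (!all(need %in% names(fits)))
    stopf("build_map_table: fits must contain %s", paste(need, collapse = ", "))
  map <- fits[fits$oscillating & !is.na(fits$phase_deg), , drop = FALSE]
  map <- map[order(map$phase_deg), , drop = FALSE]
  map$peak_hour <- phase_to_hour(map$phase_deg)
  map$molt_upregulated <- if (is.null(molt_genes)) FALSE
                          else map$gene_id %in% molt_genes
  map$tissue_class <- if (is.null(enriched_genes)) "non-specific"
                      else ifelse(map$gene_id %in% enriched_genes, tissue,
                                  "non-specific")
  if (!is.null(signalp_scores)) {
    sc <- signalp_scores[map$gene_id]
    if (anyNA(sc))
      warnf("build_map_table: %d gene(s) missing a signal-peptide score; treated as non-secreted",
            sum(is.na(sc)))
    map$signalp_score <- unname(sc)
    map$secreted <- !is.na(sc) & sc >= sp_cutoff
  }
  rownames(map) <- NULL
  attr(map, "bin_counts") <- tabulate(map$peak_hour, nbins = 8L)
  class(map) <- c("moltmap_map", "data.frame")
  map
}

#' Overlay a molt-upregulated gene set on the map
#'
#' Counts, for each of the eight hourly bins, how many oscillating map
#' genes belong to the molt-upregulated set. Set members absent from the
#' map are reported in a warning and excluded.
#'
#' @param map a `moltmap_map` table.
#' @param molt_genes character vector of molt-upregulated gene ids.
#' @return Named integer vector of per-bin counts (h1..h8).
#' @export
overlay_molt <- function(map, molt_genes) {
  if (length(molt_genes) == 0L)
    stopf("overlay_molt: empty molt gene set")
  missing <- setdiff(molt_genes, map$gene_id)
  if (length(missing) > 0L)
    warnf("overlay_molt: %d molt gene(s) absent from the map were dropped",
          length(missing))
  hit <- map$gene_id %in% molt_genes
  counts <- tabulate(map$peak_hour[hit], nbins = 8L)
  stats::setNames(counts, sprintf("h%d", 1:8))
}

#' Locate the peak molting hour from overlay counts
#'
#' Returns the hourly bin with the highest molt-overlap count. On ties the
#' earliest tied bin is returned with a warning.
#'
#' @param overlap_counts numeric vector of 8 per-bin counts.
#' @return Integer bin in 1..8.
#' @export
peak_molt_hour <- function(overlap_counts) {
  if (length(overlap_counts) != 8L)
    stopf("peak_molt_hour: expected 8 per-bin counts")
  if (all(overlap_counts == 0))
    stopf("peak_molt_hour: all overlap counts are zero")
  top <- which(overlap_counts == max(overlap_counts))
  if (length(top) > 1L)
    warnf("peak_molt_hour: tie between bins %s; returning the earliest",
          paste(top, collapse = ","))
  as.integer(top[1L])
}
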