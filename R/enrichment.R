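# Tissue enrichment, secretome partition and abundance statistics.

#' Classify genes enriched in a target tissue
#'
#' A gene is enriched when its expression in the target tissue exceeds
#' `fold` times its expression in the comparison tissues and reaches the
#' `min_tpm` abundance floor. The comparison is against every other tissue
#' (i.e. the maximum) by default — the strictest reading of "enriched
#' relative to all other tissues" — or against their mean with
#' `compare = "mean"`.
#'
#' @param mat gene x tissue TPM matrix with row and column names.
#' @param target tissue column to test (default "pharynx").
#' @param fold required fold enrichment (default 1.5, strict inequality).
#' @param min_tpm abundance floor in TPM (default 25, inclusive).
#' @param compare "max" (every other tissue) or "mean" (their average).
#' @return Character vector of enriched gene ids.
#' @export
classify_tissue_enriched <- function(mat, target = "pharynx", fold = 1.5,
                                     min_tpm = 25,
                                     compare = c("max", "mean")) {
  compare <- match.arg(compare)
  if (ncol(mat) < 2L)
    stopf("classify_tissue_enriched: need at least 2 tissues")
  if (!target %in% colnames(mat))
    stopf("classify_tissue_enriched: tissue '%s' not in matrix", target)
  if (any(mat < 0))
    stopf("classify_tissue_enriched: negative expression values")
  tv <- mat[, target]
  others <- mat[, setdiff(colnames(mat), target), drop = FALSE]
  ref <- if (compare == "max") apply(others, 1L, max) else rowMeans(others)
  rownames(mat)[tv > fold * ref & tv >= min_tpm]
}

#' Partition genes into secreted and non-secreted sets
#'
#' A gene is predicted secreted when its signal-peptide score is at least
#' `cutoff` (0.45, inclusive). Genes without a score are treated as
#' non-secreted with a warning. The two sets partition the input.
#'
#' @param genes character vector of gene ids.
#' @param signalp_scores named numeric vector of signal-peptide scores.
#' @param cutoff score threshold, inclusive (default 0.45).
#' @return List with `secreted` and `non_secreted` character vectors.
#' @export
partition_secretome <- function(genes, signalp_scores, cutoff = 0.45) {
  sc <- signalp_scores[genes]
  if (anyNA(sc))
    warnf("partition_secretome: %d gene(s) without a score treated as non-secreted",
          sum(is.na(sc)))
  sec <- !is.na(sc) & sc >= cutoff
  list(secreted = genes[sec], non_secreted = genes[!sec])
}

#' Per-bin transcript abundance profile of a gene set
#'
#' Averages expression over the genes of a set peaking in each hourly bin
#' and tests each bin against the global mean with a two-tailed one-sample
#' Student's t-test. By default the global mean is computed over the set
#' itself (so the abundance-weighted mean of the bin means reproduces it);
#' a reference mean computed over a wider gene universe — e.g. all map
#' genes — can be supplied instead.
#'
#' @param expression named numeric vector of per-gene transcript abundance
#'   (TPM) in the chosen tissue.
#' @param peak_hours named integer vector of hourly bins per gene.
#' @param gene_set genes to profile (default: all genes of `expression`).
#' @param global_mean optional externally computed reference mean.
#' @param n_bins number of hourly bins (default 8).
#' @return data.frame with bin, n, mean, sem, p; the reference mean is in
#'   `attr(, "global_mean")`.
#' @export
bin_abundance_profile <- function(expression, peak_hours,
                                  gene_set = names(expression),
                                  global_mean = NULL, n_bins = 8L) {
  miss <- setdiff(gene_set, names(expression))
  if (length(miss) > 0L)
    stopf("bin_abundance_profile: %d gene(s) lack an expression value",
          length(miss))
  miss_h <- setdiff(gene_set, names(peak_hours))
  if (length(miss_h) > 0L)
    stopf("bin_abundance_profile: %d gene(s) lack a peak hour", length(miss_h))
  vals <- expression[gene_set]
  hrs <- peak_hours[gene_set]
  if (is.null(global_mean)) global_mean <- mean(vals)

  rows <- lapply(seq_len(n_bins), function(b) {
    x <- vals[!is.na(hrs) & hrs == b]
    n <- length(x)
    if (n == 0L) {
      warnf("bin_abundance_profile: bin %d is empty", b)
      return(data.frame(bin = b, n = 0L, mean = NA_real_, sem = NA_real_,
                        p = 1))
    }
    if (n == 1L)
      warnf("bin_abundance_profile: bin %d has a single gene; p set to 1", b)
    data.frame(bin = b, n = n, mean = mean(x),
               sem = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_,
               p = one_sample_p(x, global_mean))
  })
  out <- do.call(rbind, rows)
  attr(out, "global_mean") <- global_mean
  out
}

#' Summarise cell-cluster expression into cell types
#'
#' Two summary modes per cell type: `"average"` takes the per-gene mean
#' over the listed clusters; `"max-average"` takes all values from the
#' single cluster whose average over the gene set is highest — the cluster
#' is chosen once per cell type, not per gene, which avoids diluting a
#' cell type whose clusters differ in time rather than space.
#'
#' @param mat gene x cluster expression matrix.
#' @param grouping named list; each element is a list with `clusters`
#'   (character vector of cluster columns) and `mode` ("average" or
#'   "max-average").
#' @param gene_set genes over which "max-average" ranks clusters (default:
#'   all rows).
#' @return gene x cell-type matrix.
#' @export
cluster_summary <- function(mat, grouping, gene_set = rownames(mat)) {
  all_cl <- unlist(lapply(grouping, `[[`, "clusters"))
  if (anyDuplicated(all_cl))
    stopf("cluster_summary: cluster(s) %s appear in more than one cell type",
          paste(unique(all_cl[duplicated(all_cl)]), collapse = ","))
  unknown <- setdiff(all_cl, colnames(mat))
  if (length(unknown) > 0L)
    stopf("cluster_summary: unknown cluster label(s) %s",
          paste(unknown, collapse = ","))
  out <- vapply(grouping, function(g) {
    mode <- match.arg(g$mode, c("average", "max-average"))
    sub <- mat[, g$clusters, drop = FALSE]
    if (mode == "average") {
      rowMeans(sub)
    } else {
      best <- which.max(colMeans(sub[gene_set, , drop = FALSE]))
      sub[, best]
    }
  }, numeric(nrow(mat)))
  rownames(out) <- rownames(mat)
  out
}

#' Flag bins whose expression exceeds the bin two hours earlier
#'
#' One-sided two-sample Student's t-test (equal variance) of each bin's
#' per-gene values against the bin `lag` hours before it; a bin is flagged
#' when p < `p_cutoff`. The first `lag` bins have no comparator and are
#' never flagged; bins with fewer than two genes are never flagged and
#' produce a warning.
#'
#' @param values numeric per-gene expression values.
#' @param bins integer hourly bin (1..n_bins) per gene.
#' @param lag comparison offset in bins (default 2).
#' @param p_cutoff significance threshold (default 0.01).
#' @param n_bins number of bins (default 8).
#' @return data.frame with bin, p (NA where untestable), flagged.
#' @export
lagged_bin_test <- function(values, bins, lag = 2L, p_cutoff = 0.01,
                            n_bins = 8L) {
  if (length(values) != length(bins))
    stopf("lagged_bin_test: values and bins lengths differ")
  p <- rep(NA_real_, n_bins)
  for (b in seq.int(lag + 1L, n_bins)) {
    x <- values[bins == b]
    y <- values[bins == b - lag]
    if (length(x) < 2L || length(y) < 2L) {
      warnf("lagged_bin_test: bin %d or its comparator has < 2 genes; not flagged", b)
      next
    }
    p[b] <- tryCatch(
      stats::t.test(x, y, alternative = "greater",
                    var.equal = TRUE)$p.value,
      error = function(e) 1)
  }
  data.frame(bin = seq_len(n_bins), p = p,
             flagged = !is.na(p) & p < p_cutoff)
}

#' Edges-per-node density of an interaction network
#'
#' Given a node set and an ingested edge list, counts the unique
#' undirected edges whose two endpoints both belong to the node set
#' (self-loops and edges touching outside nodes are dropped with a
#' warning) and reports edges per node.
#'
#' @param node_set character vector of node ids.
#' @param edge_list two-column data.frame or matrix of edges.
#' @return List with n_nodes, n_edges and density (= n_edges / n_nodes).
#' @export
network_density <- function(node_set, edge_list) {
  if (length(node_set) == 0L)
    stopf("network_density: empty node set")
  e <- as.data.frame(edge_list, stringsAsFactors = FALSE)
  if (ncol(e) < 2L) stopf("network_density: edge list needs two columns")
  a <- as.character(e[[1L]]); b <- as.character(e[[2L]])
  keep <- a %in% node_set & b %in% node_set & a != b
  if (any(!keep))
    warnf("network_density: %d edge(s) outside the node set (or self-loops) dropped",
          sum(!keep))
  key <- unique(paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
  list(n_nodes = length(unique(node_set)), n_edges = length(key),
       density = length(key) / length(unique(node_set)))
}
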