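# Plain-text readers and writers for the pipeline's tabular interfaces.

#' Write a table as tab-separated text with comment-header provenance
#'
#' @param x data.frame (or matrix) to write.
#' @param path output path.
#' @param comments optional character vector written as leading `#` lines
#'   (thresholds, seeds, versions).
#' @export
write_tsv <- function(x, path, comments = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table, skipping `#` comment lines
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a gene x timepoint expression table
#'
#' Expects a TSV whose first column is the gene id and whose remaining
#' column names encode hours (e.g. `h0`, `h1`, ...).
#'
#' @param path input path.
#' @return Numeric matrix with gene-id rownames.
#' @export
read_timecourse <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a one-id-per-line gene list
#'
#' @param path input path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a gene x tissue (or cluster) TPM matrix
#'
#' @param path input path (first column gene id).
#' @return Numeric matrix.
#' @export
read_tissue_matrix <- function(path) read_timecourse(path)

#' Read a two-column signal-peptide score table
#'
#' @param path TSV with columns protein_id and signalp_score.
#' @return Named numeric vector of scores.
#' @export
read_signalp_scores <- function(path) {
  df <- read_tsv(path)
  stats::setNames(as.numeric(df[[2L]]), df[[1L]])
}

#' Write generated pipeline inputs to a directory
#'
#' Serialises a synthetic dataset the way external inputs are expected:
#' time course, truth and score tables as TSV, the proteome as FASTA,
#' disorder tracks as per-protein probability strings, the molt list as
#' plain text and the configuration as JSON.
#'
#' @param cfg the [sim_config()] used.
#' @param sim list from [gen_timecourse()].
#' @param tissue matrix from [gen_tissue_matrix()].
#' @param proteome list from [gen_proteome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(cfg, sim, tissue, proteome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("seed=%d n_genes=%d", cfg$seed, cfg$n_genes)
  write_tsv(data.frame(gene_id = rownames(sim$expr), sim$expr,
                       check.names = FALSE),
            file.path(dir, "timecourse.tsv"), hdr)
  write_tsv(sim$truth, file.path(dir, "truth.tsv"), hdr)
  write_tsv(data.frame(gene_id = rownames(tissue), tissue,
                       check.names = FALSE),
            file.path(dir, "tissue_tpm.tsv"), hdr)
  write_tsv(proteome$signalp, file.path(dir, "signalp.tsv"), hdr)
  writeLines(sim$truth$gene_id[sim$truth$molt],
             file.path(dir, "molt_genes.txt"))
  Biostrings::writeXStringSet(proteome$proteins,
                              file.path(dir, "proteome.fa"))
  tracks <- vapply(proteome$disorder,
                   function(p) paste(sprintf("%.2f", p), collapse = ","), "")
  write_tsv(data.frame(protein_id = names(tracks), track = unname(tracks)),
            file.path(dir, "disorder_tracks.tsv"), hdr)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
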