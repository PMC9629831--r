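# Low-complexity family discovery: pairwise identity, single-linkage
# clustering, center-star alignment and position frequency matrices.

align_pair <- function(a, b) {
  blosum <- get_blosum62()
  Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                Biostrings::AAString(b),
                                substitutionMatrix = blosum,
                                gapOpening = 10, gapExtension = 0.5,
                                type = "global")
}

get_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

identity_from_aligned <- function(p, s, gap_included = FALSE) {
  pc <- seq_chars(p); sc <- seq_chars(s)
  both <- pc != "-" & sc != "-"
  matches <- sum(pc == sc & both)
  denom <- if (gap_included) length(pc) else sum(both)
  if (denom == 0L) return(0)
  100 * matches / denom
}

#' Percent identity of two globally aligned sequences
#'
#' Global (Needleman-Wunsch) alignment with affine gaps (BLOSUM62, gap
#' open 10, extend 0.5); identity is 100 x identical aligned pairs over
#' the columns where both sequences carry a residue. Gap-excluded identity
#' is robust to terminal-gap inflation; `gap_included = TRUE` divides by
#' all alignment columns instead.
#'
#' @param seqA,seqB canonical protein sequence strings (signal peptides
#'   should be trimmed beforehand for secreted proteins).
#' @param gap_included divide by all alignment columns.
#' @return Percent identity in \[0, 100].
#' @export
pairwise_identity <- function(seqA, seqB, gap_included = FALSE) {
  if (nchar(seqA) == 0L || nchar(seqB) == 0L)
    stopf("pairwise_identity: empty sequence")
  aln <- align_pair(seqA, seqB)
  identity_from_aligned(as.character(Biostrings::alignedPattern(aln)),
                        as.character(Biostrings::alignedSubject(aln)),
                        gap_included)
}

#' All-against-all percent identity matrix
#'
#' @param proteins named character vector or `Biostrings::AAStringSet`
#'   (unique ids required).
#' @param gap_included see [pairwise_identity()].
#' @return Symmetric numeric matrix with 100 on the diagonal, protein ids
#'   as dimnames.
#' @export
build_identity_matrix <- function(proteins, gap_included = FALSE) {
  seqs <- as.character(proteins)
  if (is.null(names(seqs))) names(seqs) <- names(proteins)
  ids <- names(seqs)
  if (length(seqs) < 2L)
    stopf("build_identity_matrix: need at least 2 proteins")
  if (is.null(ids) || anyDuplicated(ids))
    stopf("build_identity_matrix: protein ids must be present and unique")
  n <- length(seqs)
  im <- matrix(100, n, n, dimnames = list(ids, ids))
  blosum <- get_blosum62()
  for (j in 2:n) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[1:(j - 1L)]), seqs[j],
      substitutionMatrix = blosum, gapOpening = 10, gapExtension = 0.5,
      type = "global")
    pc <- as.character(Biostrings::alignedPattern(aln))
    sc <- as.character(Biostrings::alignedSubject(aln))
    for (i in seq_len(j - 1L)) {
      im[i, j] <- im[j, i] <-
        identity_from_aligned(pc[i], sc[i], gap_included)
    }
  }
  im
}

#' Discover protein families by single-linkage identity clustering
#'
#' Proteins are nodes; pairs with identity at or above the threshold are
#' edges; connected components with at least `min_family_size` members
#' become families, labelled F1, F2, ... by descending size and then by
#' the lexicographically smallest member id (so labels are stable under
#' input permutation). Everything else is a singleton.
#'
#' @param identity_matrix symmetric percent-identity matrix with id
#'   dimnames.
#' @param identity_threshold percent identity linking two proteins
#'   (default 55, inclusive). Gap-excluded identity between unrelated but
#'   similarly composition-biased proteins can reach 30-40% by chance, so
#'   the default sits between that background and the within-family
#'   identities (>60% at realistic divergence).
#' @param min_family_size minimum family size (default 3).
#' @return List with `assignment` (named character: family label or
#'   "singleton") and `families` (named list of sorted member ids).
#' @export
cluster_families <- function(identity_matrix, identity_threshold = 55,
                             min_family_size = 3L) {
  ids <- rownames(identity_matrix)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (identity_matrix[i, j] >= identity_threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  groups <- split(ids, comp)
  fams <- groups[vapply(groups, length, 1L) >= min_family_size]
  fams <- lapply(fams, sort)
  if (length(fams) > 0L) {
    ord <- order(-vapply(fams, length, 1L),
                 vapply(fams, `[`, "", 1L))
    fams <- fams[ord]
    names(fams) <- sprintf("F%d", seq_along(fams))
  } else {
    fams <- stats::setNames(list(), character(0))
  }
  assignment <- stats::setNames(rep("singleton", n), ids)
  for (f in names(fams)) assignment[fams[[f]]] <- f
  list(assignment = assignment, families = fams)
}

# number of gap columns opened before/after each center residue in one
# pairwise alignment (slots 0..Lc), given the aligned center string
center_gap_slots <- function(center_aligned) {
  cc <- seq_chars(center_aligned)
  slots <- integer(sum(cc != "-") + 1L)
  k <- 1L
  for (ch in cc) {
    if (ch == "-") slots[k] <- slots[k] + 1L else k <- k + 1L
  }
  slots
}

#' Center-star multiple alignment of a protein family
#'
#' The member with the highest summed pairwise identity to the others is
#' the center; every member is globally aligned to it and the pairwise
#' alignments are merged under the once-a-gap-always-a-gap rule. Adequate
#' for the highly similar within-family sequences this pipeline produces;
#' not a general MSA engine. Degapping any output row reproduces that
#' input sequence exactly.
#'
#' @param family_sequences named character vector (>= 2 sequences).
#' @return Named character vector of equal-width aligned sequences, input
#'   order preserved; the center id is in `attr(, "center")`.
#' @export
center_star_msa <- function(family_sequences) {
  seqs <- as.character(family_sequences)
  if (is.null(names(seqs))) names(seqs) <- names(family_sequences)
  ids <- names(seqs)
  if (length(seqs) < 2L) stopf("center_star_msa: need at least 2 sequences")
  im <- build_identity_matrix(seqs)
  score <- rowSums(im) - 100
  center <- ids[order(-score, ids)][1L]
  others <- setdiff(ids, center)
  cseq <- seqs[[center]]
  lc <- nchar(cseq)

  alns <- lapply(others, function(id) {
    a <- align_pair(cseq, seqs[[id]])
    list(center = as.character(Biostrings::alignedPattern(a)),
         member = as.character(Biostrings::alignedSubject(a)))
  })
  names(alns) <- others
  slot_mat <- vapply(alns, function(a) center_gap_slots(a$center),
                     integer(lc + 1L))
  master <- if (length(others)) apply(slot_mat, 1L, max) else integer(lc + 1L)

  expand_member <- function(a) {
    cc <- seq_chars(a$center); mm <- seq_chars(a$member)
    out <- character(0)
    k <- 1L; buf <- character(0)
    flush <- function(buf, k) c(buf, rep("-", master[k] - length(buf)))
    for (idx in seq_along(cc)) {
      if (cc[idx] == "-") {
        buf <- c(buf, mm[idx])
      } else {
        out <- c(out, flush(buf, k), mm[idx])
        buf <- character(0)
        k <- k + 1L
      }
    }
    out <- c(out, flush(buf, k))
    paste(out, collapse = "")
  }
  center_row <- {
    cc <- seq_chars(cseq)
    out <- character(0)
    for (k in seq_len(lc))
      out <- c(out, rep("-", master[k]), cc[k])
    paste(c(out, rep("-", master[lc + 1L])), collapse = "")
  }
  rows <- c(stats::setNames(list(center_row), center),
            lapply(alns, expand_member))
  res <- unlist(rows)[ids]
  attr(res, "center") <- center
  res
}

#' Position frequency matrix of an alignment
#'
#' Column-wise residue frequencies over all rows; the residue frequencies
#' plus the gap fraction sum to one in every column, and the column
#' occupancy (one minus the gap fraction) is the stack width of a sequence
#' logo. The residue colouring partition is attached as
#' `attr(, "residue_classes")`.
#'
#' @param alignment named character vector of equal-width aligned
#'   sequences.
#' @return Numeric matrix, 21 rows (20 residues plus "-") x alignment
#'   columns; occupancy in `attr(, "occupancy")`.
#' @export
position_frequency_matrix <- function(alignment) {
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L)
    stopf("position_frequency_matrix: ragged alignment")
  chars <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  ncolumns <- ncol(chars)
  lv <- c(AA20, "-")
  pfm <- vapply(seq_len(ncolumns), function(j) {
    tab <- table(factor(chars[, j], levels = lv))
    as.numeric(tab) / nrow(chars)
  }, numeric(length(lv)))
  rownames(pfm) <- lv
  attr(pfm, "occupancy") <- 1 - pfm["-", ]
  attr(pfm, "residue_classes") <- residue_classes
  pfm
}

#' Per-family temporal and property summary
#'
#' One row per discovered family: member count, median peak hour, the
#' per-bin peak-hour distribution, and mean +/- SEM of every numeric
#' property column. Families are ordered by median peak hour (ties by
#' label), reflecting their successive expression waves.
#'
#' @param assignment named character vector from [cluster_families()].
#' @param map_table `moltmap_map` data.frame (gene_id, peak_hour).
#' @param property_table data.frame with protein_id plus numeric property
#'   columns (pct_lcr, pct_idr, predictor scores, ...).
#' @return data.frame, one row per family; the peak-hour distributions in
#'   `attr(, "hour_tables")`.
#' @export
family_profile <- function(assignment, map_table, property_table) {
  fams <- setdiff(unique(assignment), "singleton")
  if (length(fams) == 0L)
    return(data.frame(family = character(0), n = integer(0),
                      median_peak_hour = numeric(0)))
  props <- names(property_table)[vapply(property_table, is.numeric, TRUE)]
  rows <- lapply(fams, function(f) {
    members <- names(assignment)[assignment == f]
    hrs <- map_table$peak_hour[match(members, map_table$gene_id)]
    if (anyNA(hrs))
      warnf("family_profile: %d member(s) of %s missing from the map excluded",
            sum(is.na(hrs)), f)
    pr <- property_table[match(members, property_table$protein_id), ,
                         drop = FALSE]
    row <- data.frame(family = f, n = length(members),
                      median_peak_hour = stats::median(hrs, na.rm = TRUE))
    for (p in props) {
      x <- pr[[p]][!is.na(pr[[p]])]
      row[[paste0("mean_", p)]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0("sem_", p)]] <- if (length(x) > 1L)
        stats::sd(x) / sqrt(length(x)) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$median_peak_hour, out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hour_tables") <- lapply(stats::setNames(fams, fams), function(f) {
    members <- names(assignment)[assignment == f]
    hrs <- map_table$peak_hour[match(members, map_table$gene_id)]
    tabulate(hrs[!is.na(hrs)], nbins = 8L)
  })
  out
}
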