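# SEG low-complexity detection: windowed Shannon entropy triggering plus
# compositional-probability refinement.

#' Shannon entropy of a residue window
#'
#' The complexity measure used by SEG: `K2 = -sum (n_i/L) log2(n_i/L)` in
#' bits, over the residues present in the window. A homopolymer scores 0;
#' a window of L distinct residues scores log2(L).
#'
#' @param window residue string (canonical 20-letter alphabet).
#' @return Entropy in bits.
#' @export
window_entropy <- function(window) {
  chars <- seq_chars(window)
  if (length(chars) < 1L) stopf("window_entropy: empty window")
  check_canonical(chars, "window")
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

# vectorised window entropies for one integer-coded sequence:
# returns K2 for every window of width W (length n - W + 1)
window_entropies <- function(codes, W) {
  n <- length(codes)
  nw <- n - W + 1L
  counts <- matrix(0L, nrow = 20L, ncol = nw)
  for (r in 1:20) {
    cs <- c(0L, cumsum(codes == r))
    counts[r, ] <- cs[(W + 1L):(n + 1L)] - cs[1:nw]
  }
  p <- counts / W
  lp <- ifelse(p > 0, p * log2(p), 0)
  -colSums(lp)
}

# log compositional probability P0 = Omega * F / 20^L for a composition
# count vector over the 20 residue classes (natural log); used by the
# refinement stage and by the brute-force test oracle.
log_p0 <- function(counts) {
  L <- sum(counts)
  log_omega <- lgamma(L + 1) - sum(lgamma(counts + 1))
  r <- table(counts)  # multiplicities of identical counts, zeros included
  log_f <- lgamma(21) - sum(lgamma(r + 1))
  log_omega + log_f - L * log(20)
}

# refinement: the subsequence of `codes` minimising log P0, computed
# incrementally in O(m^2) with O(1) updates of the count multiset.
# Ties (within tol) resolved longest-then-leftmost. Returns c(start, end)
# 1-based inclusive, and the log P0.
min_p0_subsequence <- function(codes, tol = 1e-9) {
  m <- length(codes)
  LG <- lgamma(seq_len(m + 22L))  # LG[k] = lgamma(k); index = value + 1
  best <- Inf; bs <- 1L; be <- 1L; blen <- 0L
  lg21 <- LG[21L]
  for (i in seq_len(m)) {
    counts <- integer(20L)
    h <- integer(m + 1L)          # h[c + 1] = #residue classes with count c
    h[1L] <- 20L
    sum_lgN <- 0                  # sum lgamma(counts + 1)
    sum_lgR <- LG[21L]            # sum over count values of lgamma(h + 1)
    for (j in i:m) {
      r <- codes[j]
      cc <- counts[r]
      # move one class from count cc to cc + 1, updating sum_lgR
      sum_lgR <- sum_lgR - LG[h[cc + 1L] + 1L]
      h[cc + 1L] <- h[cc + 1L] - 1L
      sum_lgR <- sum_lgR + LG[h[cc + 1L] + 1L]
      sum_lgR <- sum_lgR - LG[h[cc + 2L] + 1L]
      h[cc + 2L] <- h[cc + 2L] + 1L
      sum_lgR <- sum_lgR + LG[h[cc + 2L] + 1L]
      counts[r] <- cc + 1L
      sum_lgN <- sum_lgN + LG[cc + 2L] - LG[cc + 1L]
      len <- j - i + 1L
      lp0 <- (LG[len + 1L] - sum_lgN) + (lg21 - sum_lgR) - len * log(20)
      if (lp0 < best - tol || (abs(lp0 - best) <= tol && len > blen)) {
        best <- lp0; bs <- i; be <- j; blen <- len
      }
    }
  }
  list(start = bs, end = be, log_p0 = best)
}

#' Detect low-complexity regions with the SEG algorithm
#'
#' Two-stage detection at the standard stringency (window 12, trigger
#' entropy 2.2 bits, extension entropy 2.5 bits). Stage one slides a
#' window of `W` residues along the sequence; every window with entropy at
#' most `K_low` triggers, and each trigger extends to the maximal
#' contiguous run of windows with entropy at most `K_high`. Overlapping
#' residue spans of such runs merge into candidate regions. Stage two
#' reports, within each candidate region, the subsequence minimising the
#' compositional probability `P0 = Omega * F / 20^L` (computed in log
#' space; ties broken longest-then-leftmost).
#'
#' @param seq protein sequence string.
#' @param W window width in residues (default 12).
#' @param K_low trigger entropy in bits (default 2.2).
#' @param K_high extension entropy in bits (default 2.5).
#' @param on_noncanonical "error" (default) rejects sequences with
#'   non-canonical letters; "skip" treats windows containing them as
#'   high-complexity with a warning.
#' @return data.frame with one row per segment: start, end (residue
#'   positions, 0-based half-open) and trigger_entropy (the lowest window
#'   entropy in the parent region, bits). Sequences shorter than `W`
#'   return no segments with a warning.
#' @export
seg_low_complexity <- function(seq, W = 12L, K_low = 2.2, K_high = 2.5,
                               on_noncanonical = c("error", "skip")) {
  on_noncanonical <- match.arg(on_noncanonical)
  empty <- data.frame(start = integer(0), end = integer(0),
                      trigger_entropy = numeric(0))
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < W) {
    warnf("seg_low_complexity: sequence of %d residues is shorter than the window (%d); no segments", n, W)
    return(empty)
  }
  codes <- match(chars, AA20)
  bad <- is.na(codes)
  if (any(bad)) {
    if (on_noncanonical == "error")
      stopf("non-canonical residue(s) %s in sequence",
            paste(unique(chars[bad]), collapse = ","))
    warnf("seg_low_complexity: windows containing non-canonical residues skipped")
    codes[bad] <- 1L
  }
  k2 <- window_entropies(codes, W)
  if (any(bad)) {
    # mark windows touching a non-canonical residue as high-complexity
    touch <- vapply(seq_along(k2),
                    function(i) any(bad[i:(i + W - 1L)]), TRUE)
    k2[touch] <- Inf
  }
  trigger <- k2 <= K_low
  if (!any(trigger)) return(empty)
  extend <- k2 <= K_high

  # maximal runs of extendable windows that contain at least one trigger
  r <- rle(extend)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  spans <- NULL
  for (k in which(r$values)) {
    if (any(trigger[starts[k]:stops[k]]))
      spans <- rbind(spans, c(starts[k], stops[k] + W - 1L))
  }
  # merge overlapping residue spans into candidate regions
  spans <- spans[order(spans[, 1L]), , drop = FALSE]
  merged <- spans[1L, , drop = FALSE]
  for (k in seq_len(nrow(spans))[-1L]) {
    last <- nrow(merged)
    if (spans[k, 1L] <= merged[last, 2L]) {
      merged[last, 2L] <- max(merged[last, 2L], spans[k, 2L])
    } else merged <- rbind(merged, spans[k, ])
  }

  out <- lapply(seq_len(nrow(merged)), function(k) {
    a <- merged[k, 1L]; b <- merged[k, 2L]
    refined <- min_p0_subsequence(codes[a:b])
    win_in <- seq(a, b - W + 1L)
    data.frame(start = a + refined$start - 2L,       # to 0-based
               end = a + refined$end - 1L,           # half-open
               trigger_entropy = min(k2[win_in]))
  })
  do.call(rbind, out)
}

#' Percentage of a protein covered by low-complexity segments
#'
#' @param seq protein sequence string.
#' @param segments data.frame of disjoint segments from
#'   [seg_low_complexity()] (0-based half-open start/end).
#' @return Percent of residues inside segments, in \[0, 100].
#' @export
pct_lcr <- function(seq, segments) {
  n <- nchar(seq)
  if (nrow(segments) == 0L) return(0)
  100 * sum(segments$end - segments$start) / n
}
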