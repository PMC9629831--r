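# Independent brute-force oracles and small fixtures used across tests.

# naive Shannon entropy (bits) of a residue character vector
naive_entropy <- function(chars) {
  p <- as.numeric(table(chars)) / length(chars)
  -sum(p * log2(p))
}

# naive log compositional probability P0 of a residue character vector,
# computed directly from factorials (independent of the package's
# incremental implementation)
naive_log_p0 <- function(chars) {
  counts <- as.numeric(table(factor(chars, levels = c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))))
  L <- length(chars)
  log_omega <- lfactorial(L) - sum(lfactorial(counts))
  r <- as.numeric(table(counts))
  log_f <- lfactorial(20) - sum(lfactorial(r))
  log_omega + log_f - L * log(20)
}

# exhaustive SEG oracle: naive window entropies, trigger/extension runs,
# overlap-merged candidate regions, then a full scan of every subsequence
# of each region for the minimum-P0 subsequence (ties longest-then-
# leftmost, tolerance 1e-9). Coordinates 0-based half-open.
seg_oracle <- function(seq, W = 12, K_low = 2.2, K_high = 2.5) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < W) return(data.frame(start = integer(0), end = integer(0)))
  nw <- n - W + 1
  k2 <- vapply(seq_len(nw),
               function(i) naive_entropy(chars[i:(i + W - 1)]), 0)
  trigger <- k2 <= K_low
  if (!any(trigger)) return(data.frame(start = integer(0), end = integer(0)))
  extend <- k2 <= K_high

  spans <- NULL
  i <- 1
  while (i <= nw) {
    if (extend[i]) {
      j <- i
      while (j < nw && extend[j + 1]) j <- j + 1
      if (any(trigger[i:j])) spans <- rbind(spans, c(i, j + W - 1))
      i <- j + 1
    } else i <- i + 1
  }
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  merged <- spans[1, , drop = FALSE]
  if (nrow(spans) > 1) for (k in 2:nrow(spans)) {
    last <- nrow(merged)
    if (spans[k, 1] <= merged[last, 2])
      merged[last, 2] <- max(merged[last, 2], spans[k, 2])
    else merged <- rbind(merged, spans[k, ])
  }

  out <- NULL
  for (k in seq_len(nrow(merged))) {
    a <- merged[k, 1]; b <- merged[k, 2]
    best <- Inf; bs <- a; be <- a; blen <- 0
    for (i2 in a:b) for (j2 in i2:b) {
      lp0 <- naive_log_p0(chars[i2:j2])
      len <- j2 - i2 + 1
      if (lp0 < best - 1e-9 || (abs(lp0 - best) <= 1e-9 && len > blen)) {
        best <- lp0; bs <- i2; be <- j2; blen <- len
      }
    }
    out <- rbind(out, data.frame(start = as.integer(bs - 1),
                                 end = as.integer(be)))
  }
  out
}

# circular absolute difference between two phases in degrees
circ_err <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# random canonical protein string
random_protein <- function(n, alphabet = Biostrings::AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a small, fast simulation config whose fractions leave enough secreted
# pharynx-enriched genes to host three planted families
small_cfg <- function(seed = 1, ...) {
  args <- list(n_genes = 1000, frac_oscillating = 0.35,
               frac_enriched = 0.15, n_families = 3,
               family_sizes = c(5, 4, 3), seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# planted-truth family labels aligned to an assignment vector
truth_family_labels <- function(assignment, truth) {
  fl <- truth$family[match(names(assignment), truth$gene_id)]
  fl[is.na(fl)] <- "singleton"
  fl
}
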