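# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Residue colouring classes used for sequence logos
#'
#' Partition of the 20 canonical amino acids into the chemical classes used
#' when rendering position frequency matrices: polar, neutral, basic, acidic
#' and hydrophobic.
#'
#' @format A named list of character vectors; the union is the 20 canonical
#'   one-letter residue codes.
#' @export
residue_classes <- list(
  polar       = c("G", "S", "T", "Y", "C"),
  neutral     = c("Q", "N"),
  basic       = c("K", "R", "H"),
  acidic      = c("D", "E"),
  hydrophobic = c("A", "V", "L", "I", "P", "W", "F", "M")
)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# split a protein string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

check_canonical <- function(chars, what = "sequence") {
  bad <- setdiff(unique(chars), AA20)
  if (length(bad) > 0L)
    stopf("non-canonical residue(s) %s in %s", paste(bad, collapse = ","), what)
  invisible(TRUE)
}

# one-sample two-tailed Student t against a fixed null value; returns p.
# Degenerate inputs follow the package conventions: n < 2 -> 1 (caller
# warns); zero spread -> 1 when the mean equals the null value, else 0.
one_sample_p <- function(x, mu) {
  n <- length(x)
  if (n < 2L) return(1)
  s <- stats::sd(x)
  if (s == 0) return(if (isTRUE(all.equal(mean(x), mu))) 1 else 0)
  tt <- (mean(x) - mu) / (s / sqrt(n))
  2 * stats::pt(-abs(tt), df = n - 1L)
}
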