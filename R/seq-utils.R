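## Low-level sequence helpers shared by the simulator and the breakpoint
## analyzer.  Sequences cross module boundaries as plain character strings;
## Biostrings objects are used at I/O boundaries and for pattern matching.

.BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' @param n Length in bases.
#' @param gc Expected G+C fraction.
#' @return A character string of A/C/G/T.
#' @export
random_dna <- function(n, gc = 0.42) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a character sequence
#'
#' @param x DNA sequence (character).
#' @return The reverse complement, as character.
#' @export
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(reverseComplement(DNAString(x)))
}

## string as raw byte vector (fast elementwise comparison)
s2r <- function(x) charToRaw(x)
r2s <- function(x) rawToChar(x)

#' 0-based half-open substring
#'
#' @param x Character string.
#' @param start,end 0-based half-open bounds.
#' @return `x[start, end)`; "" when the span is empty.
#' @export
substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1, end)
}

## longest common prefix length of two raw vectors, tolerating isolated
## mismatches: a mismatch is skipped (and recorded) when the next `extend`
## bases all match, so that point substitutions (SNPs between strains) do
## not truncate flank alignment.  Returns list(len, snps) where snps are
## 0-based mismatch offsets before the stop position.
lcp_raw <- function(a, b, tol_snps = TRUE, extend = 8L) {
  n <- min(length(a), length(b))
  if (n == 0L) return(list(len = 0L, snps = integer()))
  eq <- a[seq_len(n)] == b[seq_len(n)]
  snps <- integer()
  i <- 1L
  repeat {
    bad <- if (i <= n) which(!eq[i:n]) else integer()
    if (!length(bad)) { i <- n + 1L; break }
    m <- i + bad[1L] - 1L            # first mismatch at position m
    if (!tol_snps) { i <- m; break }
    e <- min(extend, n - m)
    if (e > 0L && all(eq[(m + 1L):(m + e)])) {
      snps <- c(snps, m - 1L)        # isolated mismatch: record and continue
      i <- m + 1L
    } else { i <- m; break }
  }
  list(len = i - 1L, snps = snps)
}

## identity over the first n positions (anchoring check)
flank_identity <- function(a, b, n) {
  n <- min(n, length(a), length(b))
  if (n == 0L) return(0)
  mean(a[seq_len(n)] == b[seq_len(n)])
}

## longest run of character `base` at the given end of x ("head"/"tail"),
## allowing a tolerance fraction of other characters never used at run ends
terminal_run <- function(x, base, side = c("tail", "head"), min_frac = 0.9) {
  side <- match.arg(side)
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (side == "tail") ch <- rev(ch)
  n <- length(ch)
  best <- 0L
  hits <- 0L
  for (i in seq_len(n)) {
    hits <- hits + (ch[i] == base)
    if (ch[i] == base && hits / i >= min_frac) best <- i
    if (i - hits > 3L && hits / i < min_frac) break
  }
  best
}
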