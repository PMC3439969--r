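#' Micro-homology at a deletion's breakpoints
#'
#' The micro-homology (MH) of a span is the longest stretch of sequence
#' identity at its two breakpoints, i.e. the amount by which the junction
#' placement is ambiguous: the k-mer immediately inside one breakpoint
#' equals the k-mer immediately outside the other.  Length 0 means the
#' junction is blunt-ended.  The search runs in both directions, so the
#' result is placement-invariant: for a span reported anywhere within its
#' equivalence class the returned length equals the total number of
#' alternative placements, and the returned sequence is given for the
#' left-most placement.
#'
#' @param reference Reference sequence (character, or a named vector /
#'   `DNAStringSet` indexed by `sv_span$chrom`).
#' @param sv_span A [gint()] (or numeric `c(start, end)`, 0-based
#'   half-open) delimiting the deleted span.
#' @param max_mh Maximum homology length searched (bp).
#' @return List with `length`, `sequence` (left-most placement), `fwd` and
#'   `bwd` (match lengths right/left of the given placement), and
#'   `leftmost_start`.
#' @export
find_microhomology <- function(reference, sv_span, max_mh = 50) {
  if (inherits(sv_span, "gint")) {
    seq <- if (length(reference) == 1L && is.character(reference) &&
               is.null(names(reference))) reference
           else .genome_seq(reference, sv_span$chrom)
    s <- sv_span$start; e <- sv_span$end
  } else {
    seq <- as.character(reference)
    s <- sv_span[1L]; e <- sv_span[2L]
  }
  n <- nchar(seq)
  if (s >= e || e > n) stop("invalid sv_span")
  r <- s2r(seq)
  ## forward: ref[s + i] == ref[e + i]
  fwd <- 0L
  while (fwd < max_mh && e + fwd < n && r[s + fwd + 1L] == r[e + fwd + 1L])
    fwd <- fwd + 1L
  ## backward: ref[s - 1 - j] == ref[e - 1 - j]
  bwd <- 0L
  while (bwd < max_mh - fwd && s - bwd > 0 &&
         r[s - bwd] == r[e - bwd])
    bwd <- bwd + 1L
  if ((e + fwd >= n || s - bwd <= 0) && fwd + bwd < max_mh)
    warning("truncated-search: sv_span too close to a contig edge")
  k <- fwd + bwd
  ls <- s - bwd
  list(length = k,
       sequence = if (k > 0) substr0(seq, ls, ls + k) else "",
       fwd = fwd, bwd = bwd, leftmost_start = ls)
}

#' Target-site duplication and poly(A)/poly(T) status of an insertion
#'
#' Retrotransposon insertions are typically flanked by a short direct
#' repeat (the target-site duplication, TSD) and carry a poly(A) tail or
#' poly(T) head.  Depending on how the junction was decomposed the TSD may
#' sit outside the called insertion on both flanks, or one copy may have
#' been absorbed into the called insertion, so three configurations are
#' tried: flank/flank, insertion-suffix/left-flank-suffix and
#' insertion-prefix/right-flank-prefix.
#'
#' @param insertion Called inserted sequence (non-empty).
#' @param left_flank,right_flank Sequence immediately left/right of the
#'   insertion in the carrier allele.
#' @param min_tsd,max_tsd Accepted TSD length range (bp).
#' @param min_run Minimum terminal A (or leading T) run called a full
#'   poly tail; runs of `trunc_run` to `min_run - 1` are "truncated".
#' @param trunc_run See `min_run`.
#' @return List with `tsd` (sequence, "" if none), `tsd_len`, `poly_tail`
#'   (one of `polyA_tail`, `polyT_head`, `truncated`, `absent`).
#' @export
detect_tsd_polya <- function(insertion, left_flank, right_flank,
                             min_tsd = 5L, max_tsd = 30L,
                             min_run = 8L, trunc_run = 4L) {
  if (!nzchar(insertion)) stop("insertion must be non-empty")
  li <- nchar(insertion); ll <- nchar(left_flank); lr <- nchar(right_flank)
  best <- 0L; best_seq <- ""
  kmax <- min(max_tsd, li, max(ll, lr))
  sfx <- function(x, k) substring(x, nchar(x) - k + 1L, nchar(x))
  pfx <- function(x, k) substring(x, 1L, k)
  for (k in seq_len(kmax)) {
    hit <- NULL
    if (k <= ll && k <= lr && sfx(left_flank, k) == pfx(right_flank, k))
      hit <- pfx(right_flank, k)
    else if (k <= ll && k <= li && sfx(insertion, k) == sfx(left_flank, k))
      hit <- sfx(left_flank, k)
    else if (k <= lr && k <= li && pfx(insertion, k) == pfx(right_flank, k))
      hit <- pfx(right_flank, k)
    if (!is.null(hit)) { best <- k; best_seq <- hit }
  }
  if (best < min_tsd) { best <- 0L; best_seq <- "" }
  ## poly tail on the insertion body (TSD absorbed at an end is stripped)
  body <- insertion
  if (best > 0L) {
    if (sfx(insertion, best) == best_seq && best < li)
      body <- substring(insertion, 1L, li - best)
    else if (pfx(insertion, best) == best_seq && best < li)
      body <- substring(insertion, best + 1L, li)
  }
  run_a <- terminal_run(body, "A", "tail")
  run_t <- terminal_run(body, "T", "head")
  poly <- if (run_a >= min_run) "polyA_tail"
          else if (run_t >= min_run) "polyT_head"
          else if (max(run_a, run_t) >= trunc_run) "truncated"
          else "absent"
  list(tsd = best_seq, tsd_len = best, poly_tail = poly)
}
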