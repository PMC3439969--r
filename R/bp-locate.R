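#' Locate the breakpoints between a carrier and a non-carrier allele
#'
#' Mirrors the assembly-inspection procedure: walking in from both ends,
#' the first breakpoint is where the two alleles stop aligning and the
#' second where they start aligning again; the unaligned middles of the
#' two sequences are returned for micro-event calling.  Isolated point
#' mismatches (strain SNPs) do not stop the walk: a mismatch followed by
#' `extend` matching bases is recorded as a SNP and skipped.  When the
#' prefix and suffix matches overlap (micro-homology at the junction) the
#' suffix match is clipped, which places the junction at its right-most
#' position; [leftmost_normalize()] (or the `bwd` component of
#' [find_microhomology()]) recovers the canonical left-most span.
#'
#' @param carrier Allele carrying the variant (character).
#' @param noncarrier Allele without the variant (usually the reference).
#' @param min_flank Minimum alignable flank on both sides, bp.
#' @param min_ident Minimum identity over `min_flank` for anchoring.
#' @param extend Matching bases required after a mismatch for it to count
#'   as a SNP rather than the breakpoint.
#' @return List of class `junction_decomposition`: `bp1` (last matching
#'   position of the left flank, 0-based), `bp2_carrier`, `bp2_noncarrier`
#'   (first matching positions of the right flank in each allele),
#'   `carrier_middle`, `noncarrier_middle` (the unaligned middles),
#'   `snps` (data.frame `pos` in shared left-flank coordinates, plus
#'   `side`), `no_variant` (TRUE when the alleles align end to end).
#' @export
locate_breakpoints <- function(carrier, noncarrier, min_flank = 50L,
                               min_ident = 0.9, extend = 8L) {
  a <- s2r(carrier); b <- s2r(noncarrier)
  if (!length(a) || !length(b)) stop("empty sequence")
  if (flank_identity(a, b, min_flank) < min_ident ||
      flank_identity(rev(a), rev(b), min_flank) < min_ident)
    stop("unanchored-locus: flanks fail to align at >= ", min_ident,
         " identity over ", min_flank, " bp")
  L <- lcp_raw(a, b, tol_snps = TRUE, extend = extend)
  R <- lcp_raw(rev(a), rev(b), tol_snps = TRUE, extend = extend)
  bp1 <- L$len
  lcs <- min(R$len, length(a) - bp1, length(b) - bp1)
  b2c <- length(a) - lcs
  b2n <- length(b) - lcs
  mc <- substr0(carrier, bp1, b2c)
  mn <- substr0(noncarrier, bp1, b2n)
  snps <- rbind(
    if (length(L$snps)) data.frame(pos = L$snps, side = "left"),
    if (length(R$snps)) data.frame(pos = length(a) - 1L - R$snps,
                                   side = "right"))
  if (is.null(snps)) snps <- data.frame(pos = integer(), side = character())
  structure(list(bp1 = bp1, bp2_carrier = b2c, bp2_noncarrier = b2n,
                 carrier_middle = mc, noncarrier_middle = mn, snps = snps,
                 no_variant = !nzchar(mc) && !nzchar(mn)),
            class = "junction_decomposition")
}

#' Call micro-events from a junction decomposition
#'
#' Interprets the unaligned middles of the two alleles.  The longer middle
#' is the structural variant itself; the shorter one is the micro-event:
#' extra sequence in a deletion carrier is a micro-insertion, missing
#' reference sequence in an insertion carrier is a micro-deletion.
#' Inversions are recognized by reverse-complement identity between the
#' middles (micro-events appear as unmatched overhangs at the junctions),
#' and tandem duplications by the called insertion ending (or starting)
#' with a copy of the reference sequence adjacent to the junction.
#'
#' @param dec A `junction_decomposition` from [locate_breakpoints()].
#' @param reference The non-carrier (reference) allele, required to
#'   recognize duplications; NULL disables the duplication check.
#' @param min_core Minimum reverse-complement core to call an inversion,
#'   bp.
#' @param min_dup Minimum adjacent-copy length to call a duplication, bp;
#'   must exceed the TSD search ceiling of [detect_tsd_polya()] so that
#'   target-site duplications are not mistaken for tandem copies.
#' @return List with `sv_type` (`none`, `deletion`, `insertion`,
#'   `inversion`, `gain`), `sv_len`, `micro_insertion` (sequence),
#'   `micro_deletion_length`, and for gains `dup_len`.
#' @export
call_micro_events <- function(dec, reference = NULL, min_core = 30L,
                              min_dup = 50L) {
  mc <- dec$carrier_middle; mn <- dec$noncarrier_middle
  lc <- nchar(mc); ln <- nchar(mn)
  out <- list(sv_type = "none", sv_len = 0L, micro_insertion = "",
              micro_deletion_length = 0L, dup_len = 0L)
  if (dec$no_variant) return(out)
  ## inversion: the carrier middle contains the reverse complement of
  ## (most of) the reference middle
  if (lc >= min_core && ln >= min_core) {
    inv <- .inversion_decomposition(mc, mn, min_core)
    if (!is.null(inv)) {
      out$sv_type <- "inversion"
      out$sv_len <- ln
      out$micro_insertion <- inv$micro_insertion
      out$micro_deletion_length <- inv$micro_deletion_length
      return(out)
    }
  }
  if (lc > ln) {
    ## insertion-type: extra sequence in the carrier; missing reference
    ## bases at the junction are a micro-deletion
    out$sv_type <- "insertion"
    out$sv_len <- lc
    out$micro_deletion_length <- ln
    ins <- mc
    if (!is.null(reference)) {
      dup <- .strip_adjacent_dup(ins, reference, dec$bp1, min_dup)
      if (dup$dup_len > 0L) {
        out$sv_type <- "gain"
        out$dup_len <- dup$dup_len
        out$sv_len <- dup$dup_len
        ins <- dup$leftover
      }
    }
    if (out$sv_type == "gain") out$micro_insertion <- ins
    return(out)
  }
  ## deletion-type: missing reference sequence; leftover carrier middle is
  ## a micro-insertion
  out$sv_type <- "deletion"
  out$sv_len <- ln
  out$micro_insertion <- mc
  out
}

## carrier middle = [ins] + revcomp(core) or revcomp(core) + [ins], where
## core covers all but a deleted edge of the reference middle
.inversion_decomposition <- function(mc, mn, min_core) {
  rcn <- revcomp(mn)
  a <- .overlap_len(mc, rcn, "suffix_prefix")
  b <- .overlap_len(mc, rcn, "prefix_suffix")
  m <- max(a, b)
  if (m < min_core) return(NULL)
  if (a >= b) {
    list(micro_insertion = substr0(mc, 0, nchar(mc) - a),
         micro_deletion_length = nchar(mn) - a)
  } else {
    list(micro_insertion = substr0(mc, b, nchar(mc)),
         micro_deletion_length = nchar(mn) - b)
  }
}

## longest m with suffix(x, m) == prefix(y, m) (or the mirrored variant)
.overlap_len <- function(x, y, mode) {
  nx <- nchar(x); ny <- nchar(y)
  for (m in seq(min(nx, ny), 1L)) {
    ok <- if (mode == "suffix_prefix")
      substring(x, nx - m + 1L, nx) == substring(y, 1L, m)
    else substring(x, 1L, m) == substring(y, ny - m + 1L, ny)
    if (ok) return(m)
  }
  0L
}

## longest d such that the called insertion ends (or starts) with a copy
## of the reference segment adjacent to the junction at bp1
.strip_adjacent_dup <- function(ins, reference, bp1, min_dup) {
  li <- nchar(ins)
  dmax_l <- min(li, bp1)
  d_suf <- 0L
  for (d in seq_len(dmax_l)) {
    if (substring(ins, li - d + 1L, li) == substr0(reference, bp1 - d, bp1))
      d_suf <- d
  }
  dmax_r <- min(li, nchar(reference) - bp1)
  d_pre <- 0L
  for (d in seq_len(dmax_r)) {
    if (substring(ins, 1L, d) == substr0(reference, bp1, bp1 + d))
      d_pre <- d
  }
  d <- max(d_suf, d_pre)
  if (d < min_dup) return(list(dup_len = 0L, leftover = ins))
  leftover <- if (d_suf >= d_pre) substring(ins, 1L, li - d)
              else substring(ins, d + 1L, li)
  list(dup_len = d, leftover = leftover)
}
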