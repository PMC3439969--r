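#' Infer SV ancestry from an outgroup allele
#'
#' Presence/absence variants are polarized against an outgroup species:
#' if the outgroup matches the allele lacking the sequence, the
#' sequence-bearing allele arose by an ancestral insertion; if the
#' outgroup carries the sequence, the lacking allele arose by an ancestral
#' deletion.  Inversions and duplications are not polarized this way and
#' return `not_applicable`.
#'
#' @param carrier Allele carrying the SV (character sequence).
#' @param noncarrier Allele without the SV.
#' @param outgroup Outgroup allele.
#' @param sv_type SV type from [call_micro_events()].
#' @param tol Maximum residual middle length (bp) for the outgroup to
#'   "match" an allele arrangement.
#' @return One of `"ancestral_insertion"`, `"ancestral_deletion"`,
#'   `"ambiguous"`, `"not_applicable"`.
#' @export
infer_ancestry <- function(carrier, noncarrier, outgroup,
                           sv_type = "deletion", tol = 10L) {
  if (is.null(outgroup) || !nzchar(outgroup)) stop("outgroup allele required")
  if (!sv_type %in% c("deletion", "insertion"))
    return("not_applicable")
  mid_len <- function(x, y) {
    d <- tryCatch(locate_breakpoints(x, y), error = function(e) NULL)
    if (is.null(d)) return(Inf)
    max(nchar(d$carrier_middle), nchar(d$noncarrier_middle))
  }
  ## which arrangement does the outgroup match?
  to_carrier <- mid_len(outgroup, carrier)
  to_noncarrier <- mid_len(outgroup, noncarrier)
  ## identify the sequence-bearing allele (the longer arrangement)
  carrier_bears <- nchar(carrier) > nchar(noncarrier)
  bearing_d <- if (carrier_bears) to_carrier else to_noncarrier
  lacking_d <- if (carrier_bears) to_noncarrier else to_carrier
  if (lacking_d <= tol && bearing_d > tol) return("ancestral_insertion")
  if (bearing_d <= tol && lacking_d > tol) return("ancestral_deletion")
  "ambiguous"
}

#' Test SNP/SV co-segregation in a junction region
#'
#' A SNP inside the micro-homology (or target-site duplication) of an SV
#' co-segregates with the variant when every carrier strain shares the
#' same variant base and every non-carrier strain matches the reference
#' base at that position.  Partial sharing is not flagged.  Positions are
#' compared in reference coordinates over a region where carrier alleles
#' are alignment-anchored to the reference prefix (true for MH/TSD
#' regions, which lie at or left of the first breakpoint).
#'
#' @param reference_allele Reference sequence of the locus.
#' @param strain_alleles Named character vector of per-strain sequences.
#' @param sdp An [sdp()] giving carrier status per strain (1 = carrier).
#' @param region Numeric `c(start, end)`, 0-based half-open, in reference
#'   coordinates (e.g. the MH or TSD span).
#' @return List with `cosegregating` (TRUE/FALSE), `n_snps`, `positions`
#'   (0-based reference positions of co-segregating SNPs), or
#'   `not_applicable = TRUE` when the region is empty or the strain design
#'   has fewer than 2 carriers or 1 non-carrier.
#' @export
test_snp_cosegregation <- function(reference_allele, strain_alleles, sdp,
                                   region) {
  stopifnot(inherits(sdp, "sdp"))
  strains <- intersect(sdp$strain_order, names(strain_alleles))
  pres <- sdp$presence[match(strains, sdp$strain_order)]
  carriers <- strains[pres >= 1L]
  noncarr <- strains[pres == 0L]
  if (is.null(region) || diff(region) <= 0 || length(carriers) < 2L ||
      length(noncarr) < 1L)
    return(list(not_applicable = TRUE, cosegregating = FALSE, n_snps = 0L,
                positions = integer()))
  rr <- s2r(reference_allele)
  pos_hits <- integer()
  for (p in seq(region[1L], region[2L] - 1L)) {
    refb <- rr[p + 1L]
    cb <- vapply(carriers, function(s) substr(strain_alleles[[s]],
                                              p + 1L, p + 1L), "")
    nb <- vapply(noncarr, function(s) substr(strain_alleles[[s]],
                                             p + 1L, p + 1L), "")
    if (length(unique(cb)) == 1L && cb[1L] != rawToChar(refb) &&
        all(nb == rawToChar(refb)))
      pos_hits <- c(pos_hits, p)
  }
  list(not_applicable = FALSE, cosegregating = length(pos_hits) > 0L,
       n_snps = length(pos_hits), positions = pos_hits)
}

#' Classify the origin of a micro-inserted sequence
#'
#' Micro-insertions at deletion breakpoints arise from (i) small
#' intra-chromosomal or (ii) inter-chromosomal copy-number gains, or
#' (iii) retrotransposon fragments.  The sequence is matched (at >= 90%
#' identity, both strands) against the repeat library and the genome;
#' ties break in the order retrotransposon > intra > inter, the repeat
#' identity being the more specific claim.  Sequences shorter than
#' `min_origin_len` are not classified.
#'
#' @param micro_insertion The inserted sequence.
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param chrom Chromosome the SV lies on (defines "intra").
#' @param repeat_library Named character vector of repeat consensus
#'   sequences (NULL skips the retrotransposon check).
#' @param min_origin_len Minimum classifiable length, bp.
#' @param max_mismatch_frac Mismatch fraction allowed in a match.
#' @return One of `"retrotransposon"`, `"intra_chromosomal_gain"`,
#'   `"inter_chromosomal_gain"`, `"de_novo"`, `"none"`.
#' @export
classify_insertion_origin <- function(micro_insertion, genome, chrom,
                                      repeat_library = NULL,
                                      min_origin_len = 10L,
                                      max_mismatch_frac = 0.1) {
  if (nchar(micro_insertion) < min_origin_len) return("none")
  pat <- DNAString(micro_insertion)
  rcp <- reverseComplement(pat)
  mm <- floor(max_mismatch_frac * nchar(micro_insertion))
  hit <- function(subject) {
    vcountPattern(pat, subject, max.mismatch = mm) > 0 |
      vcountPattern(rcp, subject, max.mismatch = mm) > 0
  }
  if (!is.null(repeat_library) && length(repeat_library) &&
      any(hit(DNAStringSet(repeat_library))))
    return("retrotransposon")
  gs <- if (is.character(genome)) DNAStringSet(genome) else genome
  hits <- hit(gs)
  if (any(hits[names(gs) == chrom])) return("intra_chromosomal_gain")
  if (any(hits)) return("inter_chromosomal_gain")
  "de_novo"
}
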