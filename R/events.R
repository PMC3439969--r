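#' Strain distribution patterns (SDPs)
#'
#' An SDP is the ordered presence/absence vector of a variant across a
#' panel of inbred strains, written as a string such as `"11110101"`
#' (1 = SV present, 0 = absent).  Values 2, 3 and 4 are stored verbatim for
#' multi-allelic sites but interpreted only as "present, distinct allele".
#'
#' @param presence Integer vector of indicators (0/1, or 2-4 for
#'   multi-allelic sites), one per strain.
#' @param strain_order Character vector of strain names; defaults to the
#'   eight classical strains [classical_strains()].
#' @return An object of class `sdp`.
#' @export
sdp <- function(presence, strain_order = classical_strains()) {
  presence <- as.integer(presence)
  if (length(presence) != length(strain_order))
    stop("presence and strain_order lengths differ")
  if (any(is.na(presence)) || any(presence < 0 | presence > 4))
    stop("presence indicators must be in 0..4")
  structure(list(strain_order = strain_order, presence = presence),
            class = "sdp")
}

#' @rdname sdp
#' @param x An `sdp` object.
#' @param ... Unused.
#' @exportS3Method base::format
format.sdp <- function(x, ...) paste(x$presence, collapse = "")

#' @export
print.sdp <- function(x, ...) {
  cat("<sdp>", format(x), "(", paste(x$strain_order, collapse = ", "), ")\n")
  invisible(x)
}

#' @rdname sdp
#' @param string An SDP string such as `"11110101"`.
#' @export
parse_sdp <- function(string, strain_order = classical_strains()) {
  sdp(as.integer(strsplit(string, "", fixed = TRUE)[[1L]]), strain_order)
}

#' The eight classical inbred strains
#'
#' Default strain panel, in the conventional order used for SDP strings.
#' C57BL/6J is the reference strain: variants are expressed relative to its
#' genome, so its indicator is 0 for reference-relative variants.
#'
#' @return Character vector of eight strain names.
#' @export
classical_strains <- function() {
  c("A/J", "AKR/J", "BALB/cJ", "C3H/HeJ", "C57BL/6J", "CBA/J", "DBA/2J",
    "LP/J")
}

#' @rdname classical_strains
#' @export
reference_strain <- function() "C57BL/6J"

#' Breakpoint architecture of a structural variant
#'
#' Nucleotide-resolution features observed (or planted) at an SV junction:
#' micro-insertion sequence, micro-deletion length, micro-homology,
#' target-site duplication (TSD), poly(A)/poly(T) status, counts of SNPs
#' co-segregating within the micro-homology or TSD, and the origin of any
#' micro-inserted sequence.  Fields are independent: a junction may carry
#' both a micro-insertion and a micro-deletion.  An empty micro-homology
#' means the junction is blunt-ended.
#'
#' @param micro_insertion Inserted sequence at the junction ("" if none).
#' @param micro_deletion_length Number of missing reference bases (>= 0).
#' @param micro_homology Micro-homology sequence ("" = blunt).
#' @param tsd Target-site duplication sequence ("" if none).
#' @param poly_tail One of `"polyA_tail"`, `"polyT_head"`, `"truncated"`,
#'   `"absent"`, `"not_applicable"`.
#' @param snps_in_mh,snps_in_tsd Counts of co-segregating SNPs.
#' @param insertion_origin One of `"intra_chromosomal_gain"`,
#'   `"inter_chromosomal_gain"`, `"retrotransposon"`, `"de_novo"`, `"none"`.
#' @return An object of class `breakpoint_architecture`.
#' @export
breakpoint_architecture <- function(micro_insertion = "",
                                    micro_deletion_length = 0,
                                    micro_homology = "",
                                    tsd = "",
                                    poly_tail = "not_applicable",
                                    snps_in_mh = 0L,
                                    snps_in_tsd = 0L,
                                    insertion_origin = "none") {
  poly_tail <- match.arg(poly_tail, c("not_applicable", "polyA_tail",
                                      "polyT_head", "truncated", "absent"))
  insertion_origin <- match.arg(
    insertion_origin, c("none", "intra_chromosomal_gain",
                        "inter_chromosomal_gain", "retrotransposon",
                        "de_novo"))
  if (micro_deletion_length < 0) stop("micro_deletion_length must be >= 0")
  structure(list(micro_insertion = micro_insertion,
                 micro_deletion_length = as.integer(micro_deletion_length),
                 micro_homology = micro_homology,
                 tsd = tsd, poly_tail = poly_tail,
                 snps_in_mh = as.integer(snps_in_mh),
                 snps_in_tsd = as.integer(snps_in_tsd),
                 insertion_origin = insertion_origin),
            class = "breakpoint_architecture")
}

#' Structural variant events
#'
#' A typed SV with its reference footprint, any inserted sequence, ordered
#' sub-components for complex architectures, a strain distribution pattern
#' and (for simulated events) the true breakpoint architecture.  Components
#' of a complex event must be directly adjacent on the reference: complex
#' SVs are defined as two or more variants abutting with no intervening DNA
#' of normal structure.
#'
#' @param id Locus identifier.
#' @param code Architecture code from [sv_codes()].
#' @param ref_interval [gint()]: the deleted/inverted/duplicated span, or a
#'   zero-length anchor (start == end, built internally) for pure
#'   insertions; pass `insertion_point` for those instead.
#' @param inserted_sequence Novel sequence carried by the variant ("" if
#'   none).
#' @param components Ordered list of sub-events, each a list with at least
#'   `type` (one of `"del"`, `"inv"`, `"dup"`, `"ins"`, `"nml"`, `"copy"`)
#'   and `interval`.  Simple events have exactly one component; components
#'   of a complex event must tile a contiguous reference span.
#' @param sdp An [sdp()] or NULL.
#' @param truth_architecture A [breakpoint_architecture()] or NULL.
#' @param params Free-form list of extra event parameters used by
#'   [apply_sv()] (e.g. VNTR unit length, retrogene target position).
#' @return An object of class `sv_event`.
#' @export
sv_event <- function(id, code, ref_interval, inserted_sequence = "",
                     components = NULL, sdp = NULL,
                     truth_architecture = NULL, params = list()) {
  if (!code %in% sv_codes()) stop("unknown architecture code: ", code)
  complexity <- sv_complexity(code)
  if (is.null(components)) {
    components <- list(list(type = .default_component_type(code),
                            interval = ref_interval))
  }
  if (complexity == "simple" && length(components) != 1L)
    stop("simple events must have exactly one component")
  if (length(components) > 1L) {
    for (k in seq_len(length(components) - 1L)) {
      a <- components[[k]]$interval; b <- components[[k + 1L]]$interval
      if (a$end != b$start)
        stop("invalid event: components must be directly adjacent ",
             "(no intervening reference sequence)")
    }
  }
  structure(list(id = id, code = code, complexity = complexity,
                 ref_interval = ref_interval,
                 inserted_sequence = inserted_sequence,
                 components = components, sdp = sdp,
                 truth_architecture = truth_architecture, params = params),
            class = "sv_event")
}

.default_component_type <- function(code) {
  switch(code,
         DEL_UNIQUE = , DEL_REPEAT = , LARGE_DEL = , VNTR = "del",
         INV = "inv",
         INS_UNIQUE = , INS_REPEAT = "ins",
         TANDEM_DUP = , DISPERSED_GAIN = , LINKED_GAIN = "dup",
         INV_TANDEM_DUP = , INV_LINKED_GAIN = "dup",
         "del")
}

#' @export
print.sv_event <- function(x, ...) {
  cat(sprintf("<sv_event> %s  %s (%s)  %s:[%s,%s)\n", x$id, x$code,
              x$complexity, x$ref_interval$chrom, x$ref_interval$start,
              x$ref_interval$end))
  if (nzchar(x$inserted_sequence))
    cat("  inserted sequence:", nchar(x$inserted_sequence), "bp\n")
  if (!is.null(x$sdp)) cat("  sdp:", format(x$sdp), "\n")
  invisible(x)
}

#' Canonical left-most representation of an ambiguous junction
#'
#' When micro-homology flanks a deletion or insertion the same sample
#' sequence is produced by several reference placements; the canonical
#' representation records the placement with the smallest start coordinate.
#' Events without positional ambiguity (inversions, duplications) are
#' returned unchanged.  The operation is idempotent and preserves the
#' sample sequence exactly.
#'
#' @param event An [sv_event()] (deletion- or insertion-class).
#' @param genome A named [Biostrings::DNAStringSet] (or named character
#'   vector) of reference sequences.
#' @return The event with `ref_interval` (and, for insertions, the rotated
#'   `inserted_sequence`) in left-most form.
#' @export
leftmost_normalize <- function(event, genome) {
  stopifnot(inherits(event, "sv_event"))
  chromseq <- .genome_seq(genome, event$ref_interval$chrom)
  s <- event$ref_interval$start; e <- event$ref_interval$end
  is_del <- event$code %in% c("DEL_UNIQUE", "DEL_REPEAT", "LARGE_DEL") ||
    (length(event$components) == 1L && event$components[[1L]]$type == "del")
  is_ins <- event$code %in% c("INS_UNIQUE", "INS_REPEAT") ||
    (length(event$components) == 1L && event$components[[1L]]$type == "ins")
  if (is_del) {
    ## shift left while the base preceding the span equals its last base
    w <- 2000L
    while (s > 0) {
      lo <- max(0L, s - w)
      chunk <- s2r(substr0(chromseq, lo, e))
      off <- s - lo
      while (off > 0 && chunk[off] == chunk[length(chunk)]) {
        s <- s - 1; e <- e - 1
        off <- off - 1L
        chunk <- chunk[-length(chunk)]
      }
      if (off > 0 || s == 0) break
    }
    event$ref_interval <- gint(event$ref_interval$chrom, s, e)
    if (length(event$components) == 1L)
      event$components[[1L]]$interval <- event$ref_interval
  } else if (is_ins) {
    ins <- s2r(event$inserted_sequence)
    if (length(ins)) {
      p <- event$params$insertion_point
      if (is.null(p)) p <- s
      refraw <- s2r(substr0(chromseq, max(0L, p - length(ins) - 2000L), p))
      i <- length(refraw)
      while (p > 0 && i > 0 && refraw[i] == ins[length(ins)]) {
        ins <- c(ins[length(ins)], ins[-length(ins)])  # rotate right
        p <- p - 1; i <- i - 1L
      }
      event$inserted_sequence <- r2s(ins)
      event$params$insertion_point <- p
      event$ref_interval <- gint(event$ref_interval$chrom, p, p + 1)
      if (length(event$components) == 1L)
        event$components[[1L]]$interval <- event$ref_interval
    }
  }
  event
}

## fetch one chromosome as a character string from DNAStringSet / char vec
.genome_seq <- function(genome, chrom) {
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    return(genome[[chrom]])
  }
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  as.character(genome[[chrom]])
}
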