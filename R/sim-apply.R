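#' Apply a structural variant to a reference chromosome
#'
#' Rearranges the reference according to the event and returns the sample
#' haplotype together with a piecewise coordinate map from haplotype
#' positions back to reference positions.  The map is what makes exact,
#' mapper-free read simulation possible: every haplotype base either maps
#' to a reference base (on either strand) or is novel sequence.
#'
#' All 19 architecture codes are supported, including deletions separated
#' by a small normal copy, SVs nested within copy-number gains, VNTR unit
#' count changes, linked and dispersed gains, and retrogenes (a multi-exon
#' toy gene copied without introns to a distal site, direct or inverted).
#'
#' @param reference An `sv_reference`, or a named character vector of
#'   chromosome sequences.
#' @param event An [sv_event()]; `event$params` carries code-specific
#'   fields (see [make_sv_event()]).
#' @return List with `haplotype` (character), `map` (data.frame with
#'   columns `hap_start`, `hap_end`, `ref_start`, `ref_end`, `strand`;
#'   0-based half-open; strand `"*"` marks novel sequence) and `chrom`.
#' @export
apply_sv <- function(reference, event) {
  genome <- if (inherits(reference, "sv_reference")) reference$genome
            else reference
  chrom <- event$ref_interval$chrom
  chromseq <- .genome_seq(genome, chrom)
  L <- nchar(chromseq)
  if (event$ref_interval$end > L)
    stop("invalid event: interval beyond chromosome end")
  rep <- .event_pieces(event, L)
  segs <- c(list(.seg_ref(0, rep$a)), rep$segs, list(.seg_ref(rep$b, L)))
  .assemble_hap(chromseq, segs, chrom)
}

.seg_ref <- function(s, e, strand = "+")
  list(ref_start = s, ref_end = e, strand = strand, seq = NULL)
.seg_novel <- function(seq)
  list(ref_start = NA_real_, ref_end = NA_real_, strand = "*", seq = seq)

## translate an event into its replacement region [a, b) and the pieces
## that replace it on the haplotype
.event_pieces <- function(event, L) {
  code <- event$code
  iv <- event$ref_interval
  s <- iv$start; e <- iv$end
  p <- event$params
  ins <- event$inserted_sequence
  switch(code,
    DEL_UNIQUE = , DEL_REPEAT = , LARGE_DEL =
      list(a = s, b = e, segs = list()),
    DEL_NML_DEL = {
      ## adjudicated as one simple evidence unit, so the retained normal
      ## copy lives in params rather than in components
      if (is.null(p$gap_start) || is.null(p$gap_end))
        stop("DEL_NML_DEL needs params gap_start/gap_end")
      if (p$gap_start <= s || p$gap_end >= e)
        stop("invalid event: normal gap must lie strictly inside the span")
      list(a = s, b = e, segs = list(.seg_ref(p$gap_start, p$gap_end)))
    },
    INV = list(a = s, b = e, segs = list(.seg_ref(s, e, "-"))),
    DEL_INV = {
      cmp <- event$components
      invc <- Filter(function(x) x$type == "inv", cmp)[[1L]]
      list(a = s, b = e,
           segs = list(.seg_ref(invc$interval$start, invc$interval$end, "-")))
    },
    INS_UNIQUE = , INS_REPEAT = {
      pt <- if (!is.null(p$insertion_point)) p$insertion_point else s
      list(a = pt, b = pt, segs = list(.seg_novel(ins)))
    },
    TANDEM_DUP = list(a = s, b = e,
                      segs = list(.seg_ref(s, e), .seg_ref(s, e))),
    INV_TANDEM_DUP = list(a = s, b = e,
                          segs = list(.seg_ref(s, e), .seg_ref(s, e, "-"))),
    SV_IN_GAIN = {
      m1 <- p$del_in_copy[1L]; m2 <- p$del_in_copy[2L]
      if (m1 < s || m2 > e) stop("invalid event: nested deletion outside gain")
      list(a = s, b = e, segs = list(.seg_ref(s, e), .seg_ref(s, m1),
                                     .seg_ref(m2, e)))
    },
    DISPERSED_GAIN = , LINKED_GAIN = , INV_LINKED_GAIN = {
      q <- p$target
      strand <- if (code == "INV_LINKED_GAIN") "-" else "+"
      if (!is.null(p$inverted) && isTRUE(p$inverted)) strand <- "-"
      list(a = q, b = q, segs = list(.seg_ref(s, e, strand)))
    },
    VNTR = {
      u <- p$unit_len; n_ref <- p$n_ref; n_alt <- p$n_alt
      if (e - s != u * n_ref) stop("VNTR interval must equal unit * n_ref")
      if (n_alt <= n_ref) {
        list(a = s, b = e, segs = list(.seg_ref(s, s + u * n_alt)))
      } else {
        extra <- replicate(n_alt - n_ref, .seg_ref(s, s + u),
                           simplify = FALSE)
        list(a = s, b = e, segs = c(list(.seg_ref(s, e)), extra))
      }
    },
    DEL_INS = list(a = s, b = e, segs = list(.seg_novel(ins))),
    INV_INS = {
      side <- if (!is.null(p$ins_side)) p$ins_side else "right"
      segs <- if (side == "right")
        list(.seg_ref(s, e, "-"), .seg_novel(ins))
      else list(.seg_novel(ins), .seg_ref(s, e, "-"))
      list(a = s, b = e, segs = segs)
    },
    RETROGENE_FALSE_DEL = , RETROGENE_FALSE_INV = {
      ex <- p$exons  # data.frame(start, end), reference coordinates
      q <- p$target
      if (code == "RETROGENE_FALSE_DEL") {
        segs <- lapply(seq_len(nrow(ex)),
                       function(i) .seg_ref(ex$start[i], ex$end[i]))
      } else {
        segs <- lapply(rev(seq_len(nrow(ex))),
                       function(i) .seg_ref(ex$start[i], ex$end[i], "-"))
      }
      list(a = q, b = q, segs = segs)
    },
    stop("unsupported architecture code: ", code))
}

.assemble_hap <- function(chromseq, segs, chrom) {
  segs <- Filter(function(g) {
    if (g$strand == "*") nzchar(g$seq) else g$ref_end > g$ref_start
  }, segs)
  pieces <- vapply(segs, function(g) {
    if (g$strand == "*") return(g$seq)
    x <- substr0(chromseq, g$ref_start, g$ref_end)
    if (g$strand == "-") revcomp(x) else x
  }, "")
  w <- nchar(pieces)
  he <- cumsum(w); hs <- he - w
  map <- data.frame(
    hap_start = hs, hap_end = he,
    ref_start = vapply(segs, function(g) as.numeric(g$ref_start), 0),
    ref_end = vapply(segs, function(g) as.numeric(g$ref_end), 0),
    strand = vapply(segs, function(g) g$strand, ""))
  list(haplotype = paste(pieces, collapse = ""), map = map, chrom = chrom)
}

#' Construct typed SV events for the simulator
#'
#' Convenience constructor filling `components` and `params` in the layout
#' [apply_sv()] expects for each architecture code.
#'
#' @param code Architecture code from [sv_codes()].
#' @param chrom Chromosome name.
#' @param ... Code-specific parameters:
#'   \describe{
#'   \item{deletions/inversions/duplications}{`start`, `end`.}
#'   \item{DEL_NML_DEL}{`start`, `end` plus `gap_start`, `gap_end` (the
#'     retained normal copy).}
#'   \item{DEL_INV}{`start`, `end` plus `inv_start`, `inv_end`.}
#'   \item{insertions (INS_*, DEL_INS, INV_INS)}{`insertion_point` (or
#'     `start`/`end` for the deleted/inverted span) and `inserted_sequence`.}
#'   \item{gains (DISPERSED/LINKED/INV_LINKED)}{`start`, `end` (source) and
#'     `target` (insertion point of the copy).}
#'   \item{SV_IN_GAIN}{`start`, `end` and `del_in_copy = c(m1, m2)`.}
#'   \item{VNTR}{`start`, `unit_len`, `n_ref`, `n_alt`.}
#'   \item{retrogenes}{`exons` (data.frame start/end) and `target`.}
#'   }
#' @param id Event identifier.
#' @return An [sv_event()].
#' @export
make_sv_event <- function(code, chrom, ..., id = paste0("sv_", code)) {
  p <- list(...)
  components <- NULL
  inserted <- if (!is.null(p$inserted_sequence)) p$inserted_sequence else ""
  if (code == "VNTR") {
    p$end <- p$start + p$unit_len * p$n_ref
  }
  if (code %in% c("INS_UNIQUE", "INS_REPEAT")) {
    pt <- p$insertion_point
    iv <- gint(chrom, pt, pt + 1)
  } else if (code %in% c("RETROGENE_FALSE_DEL", "RETROGENE_FALSE_INV")) {
    iv <- gint(chrom, min(p$exons$start), max(p$exons$end))
  } else {
    iv <- gint(chrom, p$start, p$end)
  }
  if (code == "DEL_INV") {
    components <- list(
      list(type = "del", interval = gint(chrom, p$start, p$inv_start)),
      list(type = "inv", interval = gint(chrom, p$inv_start, p$inv_end)))
    if (p$inv_end < p$end)
      components <- c(components, list(
        list(type = "del", interval = gint(chrom, p$inv_end, p$end))))
  } else if (code == "DEL_INS") {
    components <- list(
      list(type = "del", interval = iv))
  } else if (code == "INV_INS") {
    components <- list(list(type = "inv", interval = iv))
  }
  sv_event(id = id, code = code, ref_interval = iv,
           inserted_sequence = inserted, components = components,
           params = p)
}
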