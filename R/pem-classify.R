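#' Classify a locus PEM signature into one of the 21 patterns
#'
#' Reimplements the visual-inspection logic as an ordered rule cascade,
#' evaluated from most to least specific:
#' \enumerate{
#'   \item retrogene check (exon-skipping mate geometry) -> Q6 / Q10;
#'   \item VNTR check (deletion-like span inside an annotated tandem
#'     repeat array, deviation a multiple of the unit) -> Q1 / Q7;
#'   \item gain context: gain with internal loss or inversion evidence ->
#'     H11; far-linked copy -> H10; adjacent duplication -> H8 / H9;
#'     nearby small copy with strictly normal depth -> Q5 / Q9;
#'   \item inversion family (FF/RR clusters): flanking zero depth -> H5;
#'     orphan cluster at one junction -> Q8; otherwise H4.  When the
#'     inversion is shorter than the insert the deletion-type geometry
#'     dominates and the call is made from the combined junction spans,
#'     so H5 is still recognized via its zero-depth flanks;
#'   \item deletion family: spanning long-FR pairs with zero depth ->
#'     H1 / H2 / Q4 / H3; zero depth with orphans but no spanning pairs ->
#'     Q2 / Q3;
#'   \item insertion family: orphan clusters with flat depth -> H6 / H7.
#' }
#' A signature matching no rule yields a no-call with the evidence
#' attached (explicit outcome, not an error).
#'
#' @param signature A [pem_signature()].
#' @param annotation List with optional data.frames `repeats` (`chrom`,
#'   `start`, `end`, `family`), `exons` (`chrom`, `start`, `end`,
#'   `gene_id`), `vntr` (`chrom`, `start`, `end`, `unit_len`) and the
#'   named character vector `repeat_library`.
#' @param insert_stats List with `mean` and `sd` of the insert size.
#' @param params [classifier_params()].
#' @return List of class `pattern_call`: `pattern` (or `"no_call"`),
#'   `code`, `complexity`, `confidence`, `interval`, `evidence`, `notes`.
#' @export
classify_pattern <- function(signature, annotation = list(),
                             insert_stats, params = classifier_params()) {
  sig <- signature
  locus <- sig$locus
  mu <- insert_stats[["mean"]]
  cl <- sig$clusters$clusters
  orp <- sig$clusters$orphans
  st <- sig$depth$states
  zero_runs <- st[st$state %in% c("zero", "loss"), , drop = FALSE]
  gain_runs <- st[st$state == "gain", , drop = FALSE]
  del_cl <- cl[cl$class == "long_FR", , drop = FALSE]
  inv_cl <- cl[cl$class %in% c("FF", "RR"), , drop = FALSE]
  dup_cl <- cl[cl$class == "RF", , drop = FALSE]

  call <- function(pattern, interval, notes = "") {
    structure(list(pattern = pattern,
                   code = if (pattern == "no_call") NA_character_
                          else pattern_code(pattern),
                   complexity = if (pattern == "no_call") NA_character_
                                else pattern_complexity(pattern),
                   confidence = if (pattern == "no_call") NA_character_
                                else if (grepl("^H", pattern)) "high"
                                else "questionable",
                   interval = interval, evidence = sig, notes = notes),
              class = "pattern_call")
  }

  ## (1) retrogene: mate footprints in distinct exons of one gene with no
  ## depth loss between them
  rg <- .retrogene_check(cl, annotation, st, params)
  if (!is.null(rg)) return(call(rg$pattern, rg$interval, rg$notes))

  ## (2) VNTR: deletion-like span inside an annotated tandem repeat array
  vn <- .vntr_check(del_cl, zero_runs, annotation, locus, params)
  if (!is.null(vn)) return(call(vn$pattern, vn$interval, vn$notes))

  ## (3) gain context
  if (nrow(gain_runs)) {
    g <- .gain_check(gain_runs, zero_runs, del_cl, inv_cl, dup_cl, st,
                     locus, mu, params)
    if (!is.null(g)) return(call(g$pattern, g$interval, g$notes))
  }

  ## (4) inversion family
  if (nrow(inv_cl)) {
    iv <- .span_of(inv_cl)
    if (nrow(zero_runs))
      return(call("H5", gint(locus$chrom, min(iv[1], min(zero_runs$start)),
                             max(iv[2], max(zero_runs$end))),
                  "inversion evidence with flanking zero-depth deletions"))
    near_orphan <- nrow(orp) && any(orp$start < iv[2] + mu &
                                      orp$end > iv[1] - mu)
    if (near_orphan)
      return(call("Q8", gint(locus$chrom, iv[1], iv[2]),
                  "inversion with orphaned mates at one junction"))
    return(call("H4", gint(locus$chrom, iv[1], iv[2]), "typical inversion"))
  }

  ## (5) deletion family
  if (nrow(zero_runs)) {
    span <- c(min(zero_runs$start), max(zero_runs$end))
    if (nrow(del_cl)) {
      normal_gaps <- .internal_normal_gaps(st, zero_runs)
      ## window quantization can inflate a measured gap by up to 2 windows
      if (nrow(zero_runs) >= 2 && length(normal_gaps) &&
          all(normal_gaps <= params$nml_gap + 2 * params$window))
        return(call("H3", gint(locus$chrom, span[1], span[2]),
                    "two deletions separated by small normal copy"))
      del_len <- span[2] - span[1]
      if (del_len > params$large_del)
        return(call("Q4", gint(locus$chrom, span[1], span[2]),
                    "large deletion"))
      rep_f <- .repeat_fraction(locus$chrom, span, annotation$repeats)
      return(call(if (rep_f >= params$repeat_frac) "H2" else "H1",
                  gint(locus$chrom, span[1], span[2]),
                  sprintf("deletion, repeat fraction %.2f", rep_f)))
    }
    if (nrow(orp)) {
      rep_f <- .repeat_fraction(locus$chrom, span, annotation$repeats)
      return(call(if (rep_f >= params$repeat_frac) "Q3" else "Q2",
                  gint(locus$chrom, span[1], span[2]),
                  "zero depth with orphans but no spanning pairs"))
    }
  }

  ## (6) insertion family: orphans with flat depth
  if (nrow(orp) && !nrow(zero_runs) && !nrow(gain_runs)) {
    o <- orp[which.max(orp$support), ]
    is_rep <- .orphans_match_repeats(sig$clusters$orphan_seqs,
                                     annotation$repeat_library)
    return(call(if (is_rep) "H7" else "H6",
                gint(locus$chrom, o$start, o$end),
                "orphan cluster with normal flanking depth"))
  }

  call("no_call", locus, "no rule matched; evidence attached")
}

.span_of <- function(cl) {
  c(min(cl$left_start), max(cl$right_end))
}

## lengths of normal segments lying strictly between zero/loss runs
.internal_normal_gaps <- function(st, zero_runs) {
  if (nrow(zero_runs) < 2) return(numeric())
  lo <- min(zero_runs$start); hi <- max(zero_runs$end)
  nm <- st[st$state == "normal" & st$start >= lo & st$end <= hi, ,
           drop = FALSE]
  nm$end - nm$start
}

.repeat_fraction <- function(chrom, span, repeats) {
  if (is.null(repeats) || !nrow(repeats)) return(0)
  r <- repeats[repeats$chrom == chrom, , drop = FALSE]
  if (!nrow(r)) return(0)
  ir <- IRanges::reduce(IRanges(r$start + 1, r$end))
  q <- IRanges(span[1] + 1, span[2])
  ov <- IRanges::intersect(ir, q)
  sum(IRanges::width(ov)) / (span[2] - span[1])
}

.retrogene_check <- function(cl, annotation, st, params) {
  ex <- annotation$exons
  if (is.null(ex) || !nrow(ex) || !nrow(cl)) return(NULL)
  pad <- params$exon_pad
  hit_gene <- function(s, e) {
    i <- which(ex$start - pad <= e & ex$end + pad >= s)
    unique(ex$gene_id[i])
  }
  ## phase 1: exon-skipping geometry -- a cluster with BOTH footprints in
  ## exons of the same gene and no depth loss in the skipped intron marks
  ## a retrogene (mates from the intron-less processed copy)
  gene <- NULL
  for (k in seq_len(nrow(cl))) {
    gl <- hit_gene(cl$left_start[k], cl$left_end[k])
    gr <- hit_gene(cl$right_start[k], cl$right_end[k])
    shared <- intersect(gl, gr)
    if (!length(shared)) next
    intron_lost <- any(st$state %in% c("zero", "loss") &
                         st$start >= cl$left_end[k] &
                         st$end <= cl$right_start[k])
    if (!intron_lost) { gene <- shared[1L]; break }
  }
  if (is.null(gene)) return(NULL)
  ## phase 2: orientation of the copy.  Exon-to-exon pairs inside the copy
  ## read as long-FR whichever way the copy points; what flips with an
  ## inverted copy are the pairs bridging the insertion site, which become
  ## FF/RR links anchored in the gene's exons.
  inverted <- FALSE
  for (k in which(cl$class %in% c("FF", "RR"))) {
    gl <- hit_gene(cl$left_start[k], cl$left_end[k])
    gr <- hit_gene(cl$right_start[k], cl$right_end[k])
    if (gene %in% c(gl, gr)) { inverted <- TRUE; break }
  }
  gi <- range(c(ex$start[ex$gene_id == gene], ex$end[ex$gene_id == gene]))
  list(pattern = if (inverted) "Q10" else "Q6",
       interval = gint(ex$chrom[ex$gene_id == gene][1L], gi[1], gi[2]),
       notes = sprintf("retrogene mate geometry over gene %s", gene))
}

.vntr_check <- function(del_cl, zero_runs, annotation, locus, params) {
  va <- annotation$vntr
  if (is.null(va) || !nrow(va)) return(NULL)
  if (!nrow(del_cl) && !nrow(zero_runs)) return(NULL)
  span <- if (nrow(zero_runs)) c(min(zero_runs$start), max(zero_runs$end))
          else c(min(del_cl$left_end), max(del_cl$right_start))
  va <- va[va$chrom == locus$chrom, , drop = FALSE]
  for (k in seq_len(nrow(va))) {
    ov <- max(0, min(span[2], va$end[k]) - max(span[1], va$start[k]))
    if (ov / max(1, span[2] - span[1]) < params$vntr_frac) next
    u <- va$unit_len[k]
    dev <- span[2] - span[1]
    mod <- dev %% u
    tol <- max(u / 2, params$window)
    if (min(mod, u - mod) <= tol || dev <= tol * 2) {
      pattern <- if (u <= params$microsat_unit) "Q1" else "Q7"
      return(list(pattern = pattern,
                  interval = gint(locus$chrom, va$start[k], va$end[k]),
                  notes = sprintf("tandem repeat array, unit %d bp", u)))
    }
  }
  NULL
}

.gain_check <- function(gain_runs, zero_runs, del_cl, inv_cl, dup_cl, st,
                        locus, mu, params) {
  gspan <- c(min(gain_runs$start), max(gain_runs$end))
  ## H11: SV nested within a gain -- a non-gain run sandwiched between two
  ## gain runs, or inversion-type clusters inside the gain span
  if (nrow(gain_runs) >= 2) {
    between <- st[st$start >= gspan[1] & st$end <= gspan[2] &
                    st$state != "gain", , drop = FALSE]
    if (nrow(between) && nrow(dup_cl))
      return(list(pattern = "H11", interval = gint(locus$chrom, gspan[1],
                                                   gspan[2]),
                  notes = "deletion within copy number gain"))
  }
  inv_in_gain <- nrow(inv_cl) && any(inv_cl$left_start >= gspan[1] - mu &
                                       inv_cl$right_end <= gspan[2] + mu) &&
    nrow(dup_cl)
  if (inv_in_gain)
    return(list(pattern = "H11",
                interval = gint(locus$chrom, gspan[1], gspan[2]),
                notes = "inversion within copy number gain"))
  no_loss <- !nrow(zero_runs)
  ## Q5 / Q9: a *small* gain (the defining property of a linked gain)
  ## whose discordant pairs mimic a deletion or inversion while depth
  ## stays strictly normal elsewhere
  gain_len <- sum(gain_runs$end - gain_runs$start)
  if (no_loss && gain_len <= params$small_gain_max) {
    if (nrow(del_cl))
      return(list(pattern = "Q5", interval = gint(locus$chrom, gspan[1],
                                                  gspan[2]),
                  notes = "linked small gain mimicking a deletion"))
    if (nrow(inv_cl))
      return(list(pattern = "Q9", interval = gint(locus$chrom, gspan[1],
                                                  gspan[2]),
                  notes = "inverted linked small gain mimicking an inversion"))
  }
  ## H10: copy far from its source (footprint separation > linked_max)
  allc <- rbind(del_cl, inv_cl, dup_cl)
  if (nrow(allc)) {
    sep <- allc$right_start - allc$left_end
    if (any(sep > params$linked_max))
      return(list(pattern = "H10",
                  interval = gint(locus$chrom, gspan[1], gspan[2]),
                  notes = "dispersed copy number gain"))
  }
  if (no_loss && nrow(inv_cl))
    return(list(pattern = "H9", interval = gint(locus$chrom, gspan[1],
                                                gspan[2]),
                notes = "inverted tandem duplication"))
  if (no_loss && nrow(dup_cl))
    return(list(pattern = "H8",
                interval = gint(locus$chrom, gspan[1], gspan[2]),
                notes = "tandem duplication"))
  NULL
}

.orphans_match_repeats <- function(orphan_seqs, repeat_library,
                                   min_frac = 0.5) {
  if (is.null(repeat_library) || !length(orphan_seqs)) return(FALSE)
  seqs <- unlist(orphan_seqs)
  seqs <- seqs[!is.na(seqs)]
  if (!length(seqs)) return(FALSE)
  seqs <- seqs[seq_len(min(length(seqs), 30L))]  # a sample is plenty
  lib <- DNAStringSet(repeat_library)
  hits <- vapply(seqs, function(s) {
    pat <- DNAString(s)
    mm <- as.integer(0.1 * nchar(s))
    any(vcountPattern(pat, lib, max.mismatch = mm) > 0) ||
      any(vcountPattern(reverseComplement(pat), lib, max.mismatch = mm) > 0)
  }, logical(1))
  mean(hits) >= min_frac
}

#' @export
print.pattern_call <- function(x, ...) {
  if (x$pattern == "no_call") {
    cat("<pattern_call> no-call (", x$notes, ")\n")
  } else {
    cat(sprintf("<pattern_call> %s -> %s (%s, %s)  %s:[%s,%s)\n  %s\n",
                x$pattern, x$code, x$complexity, x$confidence,
                x$interval$chrom, x$interval$start, x$interval$end, x$notes))
  }
  invisible(x)
}

#' Strain distribution pattern from per-strain pattern calls
#'
#' @param per_strain_calls Named list of [classify_pattern()] results, one
#'   per strain in `strain_order`; a strain whose call is `"no_call"` (or
#'   NULL) is scored absent.
#' @param strain_order Strain names in SDP order.
#' @param force_reference Force the reference strain to 0 (the default,
#'   appropriate for reference-relative variants).
#' @return An [sdp()].
#' @export
infer_sdp <- function(per_strain_calls, strain_order = classical_strains(),
                      force_reference = TRUE) {
  missing <- setdiff(strain_order, names(per_strain_calls))
  if (length(missing))
    stop("incomplete SDP: no call for strain(s) ",
         paste(missing, collapse = ", "))
  pres <- vapply(strain_order, function(s) {
    cl <- per_strain_calls[[s]]
    as.integer(!is.null(cl) && !is.na(cl$pattern) && cl$pattern != "no_call")
  }, integer(1))
  if (force_reference && reference_strain() %in% strain_order)
    pres[strain_order == reference_strain()] <- 0L
  sdp(pres, strain_order)
}

#' One-shot locus classification
#'
#' Convenience wrapper: extracts the signature and classifies it.
#'
#' @inheritParams pem_signature
#' @inheritParams classify_pattern
#' @return A `pattern_call`.
#' @export
classify_locus <- function(pairs, locus, annotation = list(), insert_stats,
                           params = classifier_params()) {
  sig <- pem_signature(pairs, locus, insert_stats, params)
  classify_pattern(sig, annotation, insert_stats, params)
}
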