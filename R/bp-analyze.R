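#' Full nucleotide-resolution analysis of one locus
#'
#' Runs the complete Sanger-regime workflow on a set of per-strain
#' assembled locus sequences: locate breakpoints against the reference
#' allele, call the SV and its micro-events, compute micro-homology for
#' deletions (with the canonical left-most span), detect TSD/poly(A) for
#' insertions, polarize ancestry against the outgroup, test SNP
#' co-segregation in the MH/TSD region across strains and classify the
#' origin of any micro-inserted sequence.
#'
#' @param locus A `bp_locus` (from [build_locus_alleles()]) or a list with
#'   `id`, `ref_allele`, `strain_alleles`, `outgroup_allele`.
#' @param genome Named character vector of contig sequences used for
#'   micro-insertion origin search (defaults to the locus reference
#'   alone).
#' @param repeat_library Named character vector of repeat consensus
#'   sequences for the retrotransposon origin check.
#' @param strain_order Strains in SDP order.
#' @param min_sv Minimum middle length (bp) calling a strain a carrier.
#' @return List of class `breakpoint_report`; `NULL` elements of note:
#'   `ancestry` is `"not_applicable"` for inversions/gains.
#' @export
analyze_locus <- function(locus, genome = NULL, repeat_library = NULL,
                          strain_order = NULL, min_sv = 20L) {
  ref <- locus$ref_allele
  id <- locus$id
  if (is.null(genome)) genome <- setNames(ref, id)
  strains <- names(locus$strain_alleles)
  if (is.null(strain_order)) strain_order <- strains
  decs <- lapply(locus$strain_alleles, function(s)
    locate_breakpoints(s, ref))
  is_carrier <- vapply(decs, function(d)
    !d$no_variant && max(nchar(d$carrier_middle),
                         nchar(d$noncarrier_middle)) >= min_sv, logical(1))
  pres <- as.integer(is_carrier[strain_order])
  called_sdp <- sdp(pres, strain_order)
  if (!any(is_carrier)) {
    return(structure(list(id = id, sv_type = "none", sv_span = NULL,
                          sv_len = 0L,
                          architecture = breakpoint_architecture(),
                          ancestry = "not_applicable",
                          cosegregation = list(snp_in_mh = FALSE,
                                               snp_in_tsd = FALSE),
                          sdp = called_sdp),
                     class = "breakpoint_report"))
  }
  carrier_strain <- strains[is_carrier][1L]
  carrier <- locus$strain_alleles[[carrier_strain]]
  dec <- decs[[carrier_strain]]
  evt <- call_micro_events(dec, reference = ref)
  mh <- list(length = 0L, sequence = "")
  tsd <- list(tsd = "", tsd_len = 0L, poly_tail = "not_applicable")
  sv_span <- NULL
  mh_region <- NULL; tsd_region <- NULL
  if (evt$sv_type == "deletion") {
    raw <- sv_event(id, "DEL_UNIQUE", gint(id, dec$bp1, dec$bp2_noncarrier))
    norm <- leftmost_normalize(raw, setNames(ref, id))
    sv_span <- norm$ref_interval
    mh <- find_microhomology(setNames(ref, id), sv_span)
    if (mh$length > 0L)
      mh_region <- c(sv_span$start, sv_span$start + mh$length)
  } else if (evt$sv_type == "insertion") {
    sv_span <- gint(id, dec$bp1, dec$bp1 + 1L)
    ## flanks are taken from the reference: the target site is defined
    ## there, and carrier-private SNPs inside a TSD copy must not
    ## truncate the exact duplication match
    lf <- substr0(ref, max(0L, dec$bp1 - 60L), dec$bp1)
    rf <- substr0(ref, dec$bp2_noncarrier,
                  min(nchar(ref), dec$bp2_noncarrier + 60L))
    tsd <- detect_tsd_polya(dec$carrier_middle, lf, rf)
    if (tsd$tsd_len > 0L)
      tsd_region <- c(dec$bp1 - tsd$tsd_len, dec$bp1)
  } else if (evt$sv_type == "inversion") {
    sv_span <- gint(id, dec$bp1, dec$bp2_noncarrier)
  } else if (evt$sv_type == "gain") {
    sv_span <- gint(id, dec$bp1 - evt$dup_len, dec$bp1)
  }
  ancestry <- if (evt$sv_type %in% c("deletion", "insertion") &&
                  !is.null(locus$outgroup_allele))
    infer_ancestry(carrier, ref, locus$outgroup_allele, evt$sv_type)
  else "not_applicable"
  cs_mh <- test_snp_cosegregation(ref, locus$strain_alleles, called_sdp,
                                  mh_region)
  cs_tsd <- test_snp_cosegregation(ref, locus$strain_alleles, called_sdp,
                                   tsd_region)
  arch <- breakpoint_architecture(
    micro_insertion = evt$micro_insertion,
    micro_deletion_length = evt$micro_deletion_length,
    micro_homology = mh$sequence,
    tsd = tsd$tsd,
    poly_tail = if (evt$sv_type == "insertion") tsd$poly_tail
                else "not_applicable",
    snps_in_mh = cs_mh$n_snps,
    snps_in_tsd = cs_tsd$n_snps,
    insertion_origin = if (nzchar(evt$micro_insertion))
      classify_insertion_origin(evt$micro_insertion, genome, id,
                                repeat_library)
    else if (evt$sv_type == "insertion") "retrotransposon" else "none")
  structure(list(id = id, sv_type = evt$sv_type, sv_span = sv_span,
                 sv_len = evt$sv_len, architecture = arch,
                 ancestry = ancestry,
                 cosegregation = list(snp_in_mh = isTRUE(cs_mh$cosegregating),
                                      snp_in_tsd = isTRUE(cs_tsd$cosegregating)),
                 sdp = called_sdp, carrier_strain = carrier_strain,
                 dup_len = evt$dup_len),
            class = "breakpoint_report")
}

#' @export
print.breakpoint_report <- function(x, ...) {
  cat(sprintf("<breakpoint_report> %s: %s", x$id, x$sv_type))
  if (!is.null(x$sv_span))
    cat(sprintf(" [%s,%s) len %s", x$sv_span$start, x$sv_span$end, x$sv_len))
  a <- x$architecture
  cat(sprintf("\n  micro-ins %d bp, micro-del %d bp, MH %d bp, TSD %d bp (%s)\n",
              nchar(a$micro_insertion), a$micro_deletion_length,
              nchar(a$micro_homology), nchar(a$tsd), a$poly_tail))
  cat(sprintf("  ancestry %s, SDP %s\n", x$ancestry, format(x$sdp)))
  invisible(x)
}

.report_class <- function(r) {
  switch(r$sv_type,
         deletion = if (r$ancestry == "ancestral_deletion")
           "ancestral_deletion" else "ancestral_deletion",
         insertion = "ancestral_insertion",
         inversion = "inversion",
         gain = "gain",
         NA_character_)
}

.report_feature <- function(r) {
  a <- r$architecture
  has_ins <- nzchar(a$micro_insertion)
  has_del <- a$micro_deletion_length > 0L
  if (has_ins && has_del) "both"
  else if (has_ins) "micro_ins"
  else if (has_del) "micro_del"
  else "none"
}

#' Tabulate breakpoint features by ancestry class and size bin
#'
#' Produces the survey-style summary: for each ancestry class column
#' (ancestral insertion / ancestral deletion / inversion / gain), the
#' percentage of loci with no micro-event, a micro-deletion (bins 1-34,
#' 35-200, >200 bp), a micro-insertion (1-10, 11-50, >51 bp) or both.
#' Percentages are column-normalized (each column sums to 100) and
#' invariant to report ordering.
#'
#' @param reports List of `breakpoint_report`s.
#' @return List with `counts` and `percent` (feature-by-class matrices),
#'   `n_by_class`, `complex_count` (loci with any micro-event) and
#'   `complex_fraction`.
#' @export
summarize_breakpoint_features <- function(reports) {
  if (!length(reports)) stop("at least one report required")
  classes <- c("ancestral_insertion", "ancestral_deletion", "inversion",
               "gain")
  bin_del <- function(n) if (n <= 34) "1-34 bp" else if (n <= 200)
    "35-200 bp" else ">200 bp"
  bin_ins <- function(n) if (n <= 10) "1-10 bp" else if (n <= 50)
    "11-50 bp" else ">51 bp"
  rows <- c("None",
            paste("Micro-deletion", c("1-34 bp", "35-200 bp", ">200 bp")),
            paste("Micro-insertion", c("1-10 bp", "11-50 bp", ">51 bp")),
            paste("Both", c("1-10 bp", "11-50 bp", ">51 bp")))
  counts <- matrix(0L, length(rows), length(classes),
                   dimnames = list(rows, classes))
  n_complex <- 0L
  n_used <- 0L
  for (r in reports) {
    cls <- .report_class(r)
    if (is.na(cls) || r$sv_type == "none") next
    n_used <- n_used + 1L
    a <- r$architecture
    ft <- .report_feature(r)
    row <- switch(ft,
      none = "None",
      micro_del = paste("Micro-deletion", bin_del(a$micro_deletion_length)),
      micro_ins = paste("Micro-insertion", bin_ins(nchar(a$micro_insertion))),
      both = paste("Both", bin_ins(max(nchar(a$micro_insertion),
                                       a$micro_deletion_length))))
    counts[row, cls] <- counts[row, cls] + 1L
    if (ft != "none") n_complex <- n_complex + 1L
  }
  n_by_class <- colSums(counts)
  percent <- sweep(counts, 2, pmax(n_by_class, 1L), "/") * 100
  list(counts = counts, percent = percent, n_by_class = n_by_class,
       complex_count = n_complex,
       complex_fraction = if (n_used) n_complex / n_used else 0)
}
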