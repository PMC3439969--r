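## Sequence-level locus construction for the breakpoint cohort.  Alleles
## are assembled from explicit pieces with forced mismatches at every
## junction boundary, so that planted micro-features are recovered exactly
## by the analyzer (no accidental homology extension) and round-trip tests
## can assert equality rather than approximation.

diff_base <- function(...) {
  forbidden <- unique(unlist(list(...)))
  sample(setdiff(.BASES, forbidden), 1L)
}

set_char <- function(x, pos0, ch) {   # 0-based position
  substr(x, pos0 + 1L, pos0 + 1L) <- ch
  x
}

char_at <- function(x, pos0) substr(x, pos0 + 1L, pos0 + 1L)

#' Sample breakpoint micro-features for an SV
#'
#' Draws the junction micro-architecture of an event from the per-class
#' feature frequency tables: presence and size of micro-insertions /
#' micro-deletions, micro-homology (with optionally co-segregating SNPs),
#' target-site duplication and poly(A)/poly(T) state for
#' retrotransposon-like insertions, and the origin class of any
#' micro-inserted sequence.  The draw is recorded in
#' `event$truth_architecture` and in `event$params$features` for the
#' sequence builder.
#'
#' @param event An [sv_event()] (or a bare list with `params`); may be a
#'   minimal stub when only the feature draw is needed.
#' @param config A [sim_config()].
#' @param class Ancestry class: one of `names(config$feature_freqs)`;
#'   defaults to `event$params$ancestry_class`.
#' @return The event with `truth_architecture` and `params$features`
#'   filled in.
#' @export
plant_breakpoint_features <- function(event, config, class = NULL) {
  if (is.null(class)) class <- event$params$ancestry_class
  ff <- config$feature_freqs[[class]]
  if (is.null(ff)) stop("config error: unknown ancestry class: ", class)
  row <- ff[sample.int(nrow(ff), 1L, prob = ff$prob), ]
  sz <- function() if (row$hi == 0) 0L else
    as.integer(round(runif(1, row$lo, row$hi)))
  f <- list(class = class, feature = row$feature,
            micro_ins_len = 0L, micro_del_len = 0L,
            mh_len = 0L, n_mh_snps = 0L,
            tsd_len = 0L, poly_tail = "not_applicable",
            n_tsd_snps = 0L, origin = "none")
  if (row$feature %in% c("micro_ins", "both")) f$micro_ins_len <- sz()
  if (row$feature %in% c("micro_del", "both")) f$micro_del_len <- sz()
  if (class == "ancestral_deletion") {
    ## micro-homology at deletion junctions; a small fraction carries
    ## SNPs that co-segregate with the SV and extend the homology
    if (runif(1) < config$snp_mh_prob) {
      ## room for two SNPs, each followed by enough clean homology for
      ## the breakpoint walker to read them as substitutions
      f$mh_len <- as.integer(round(runif(1, 18, max(25, config$mh_range[2]))))
      f$n_mh_snps <- 2L
    } else if (runif(1) < config$mh_prob) {
      f$mh_len <- as.integer(round(runif(1, config$mh_range[1],
                                         config$mh_range[2])))
    }
    if (f$micro_ins_len >= 10L)
      f$origin <- sample(names(config$origin_probs), 1L,
                         prob = config$origin_probs)
  }
  if (class == "ancestral_insertion") {
    if (runif(1) < config$tsd_absent_prob) {
      ## DNA-lesion integration route: no TSD, degraded poly tail
      f$tsd_len <- 0L
      f$poly_tail <- sample(c("truncated", "absent"), 1L)
    } else {
      f$tsd_len <- as.integer(round(runif(1, config$tsd_range[1],
                                          config$tsd_range[2])))
      f$poly_tail <- sample(c("polyA_tail", "polyT_head"), 1L)
      if (runif(1) < config$snp_tsd_prob) {
        f$tsd_len <- max(f$tsd_len, 10L)
        f$n_tsd_snps <- 1L
      }
    }
    f$origin <- "retrotransposon"
  }
  if (inherits(event, "sv_event") || is.list(event)) {
    event$params$features <- f
    event$truth_architecture <- breakpoint_architecture(
      micro_insertion = strrep("N", f$micro_ins_len),
      micro_deletion_length = f$micro_del_len,
      micro_homology = strrep("N", f$mh_len),
      tsd = strrep("N", f$tsd_len),
      poly_tail = f$poly_tail,
      snps_in_mh = f$n_mh_snps, snps_in_tsd = f$n_tsd_snps,
      insertion_origin = f$origin)
  }
  event
}

## draw a micro-insertion sequence of length `len` according to its origin
## class, honouring forbidden first/last bases
.draw_micro_ins <- function(len, origin, ref_P, decoy, lib, gc,
                            not_first, not_last) {
  if (len <= 0L) return("")
  pick <- function(src) {
    n <- nchar(src)
    if (n < len + 20L) return(NULL)
    for (t in 1:40) {
      o <- sample.int(n - len, 1L) - 1L
      x <- substr0(src, o, o + len)
      if (!char_at(x, 0L) %in% not_first &&
          !char_at(x, len - 1L) %in% not_last) return(x)
    }
    NULL
  }
  x <- switch(origin,
    intra_chromosomal_gain = pick(ref_P),
    inter_chromosomal_gain = if (!is.null(decoy)) pick(decoy) else NULL,
    retrotransposon = pick(lib[[sample(names(lib), 1L)]]),
    NULL)
  if (is.null(x)) {  # de novo / unclassifiable: random sequence
    x <- random_dna(len, gc)
    if (len == 1L) {
      ## a single base must differ from both junction neighbours or it is
      ## absorbed into the flank alignment
      x <- diff_base(not_first, not_last)
    } else {
      x <- set_char(x, 0L, diff_base(not_first))
      x <- set_char(x, len - 1L, diff_base(not_last))
    }
  }
  x
}

#' Build the per-strain alleles of one breakpoint-cohort locus
#'
#' Constructs the reference, carrier, non-carrier and outgroup sequences
#' of a locus carrying the planted micro-features, together with the
#' coordinate maps needed for read simulation and a strain distribution
#' pattern.  Carrier alleles are identical across carrier strains (clean,
#' error-free Sanger-regime sequence).
#'
#' @param id Locus identifier (also used as contig name).
#' @param class Ancestry class (see [breakpoint_feature_frequencies()]).
#' @param config A [sim_config()].
#' @param features Feature draw from [plant_breakpoint_features()]
#'   (`$params$features`); drawn fresh when NULL.
#' @param decoy Optional decoy chromosome (character) acting as "another
#'   chromosome" for inter-chromosomal micro-insertion origins.
#' @param flank Flank length on each side of the variant, bp.
#' @return List of class `bp_locus`: `id`, `class`, `ref_allele`,
#'   `strain_alleles`, `outgroup_allele`, `sdp`, `truth` (features plus
#'   `sv_span`, `sv_len`, `mh_region`, `tsd_region`), `maps` (per-allele
#'   piece lists for read simulation).
#' @export
build_locus_alleles <- function(id, class, config, features = NULL,
                                decoy = NULL, flank = 500L) {
  lib <- config$repeat_library
  if (is.null(lib)) lib <- default_repeat_library(config$gc_fraction)
  if (is.null(features)) {
    stub <- list(params = list())
    features <- plant_breakpoint_features(stub, config, class)$params$features
  }
  gc <- config$gc_fraction
  f <- features
  built <- switch(class,
    ancestral_deletion = .build_ad(f, config, lib, decoy, flank, gc),
    ancestral_insertion = .build_ai(f, config, lib, flank, gc),
    inversion = .build_inv(f, config, flank, gc),
    gain = .build_gain(f, config, flank, gc),
    stop("config error: unknown ancestry class: ", class))
  ## strain panel: carriers share the carrier allele, the reference strain
  ## and all other non-carriers the reference allele
  strains <- config$strain_order
  test <- setdiff(strains, reference_strain())
  carriers <- sample(test, sample(2:6, 1L))
  pres <- as.integer(strains %in% carriers)
  alleles <- setNames(
    ifelse(strains %in% carriers, built$carrier, built$ref), strains)
  maps <- lapply(strains, function(s)
    if (s %in% carriers) built$carrier_map else built$ref_map)
  names(maps) <- strains
  structure(list(id = id, class = class,
                 ref_allele = built$ref,
                 strain_alleles = alleles,
                 outgroup_allele = built$outgroup,
                 sdp = sdp(pres, strains),
                 truth = c(f, built$truth),
                 maps = maps),
            class = "bp_locus")
}

.ref_map <- function(L)
  list(list(ref_start = 0, ref_end = L, strand = "+", seq = NULL))

## -- ancestral deletion: ref = P M C M S', carrier = P M ins S' ----------
.build_ad <- function(f, config, lib, decoy, flank, gc) {
  k <- f$mh_len
  del_len <- as.integer(round(runif(1, 100, 800)))
  del_len <- max(del_len, k + 40L)
  core <- del_len - k
  P <- random_dna(flank, gc); Sp <- random_dna(flank, gc)
  M <- random_dna(k, gc); C <- random_dna(core, gc)
  ## boundary forcing (see comments at top of file)
  C <- set_char(C, 0L, diff_base(char_at(Sp, 0L)))
  C <- set_char(C, core - 1L, diff_base(char_at(P, flank - 1L)))
  ins <- ""
  if (f$micro_ins_len > 0L) {
    right_nb <- if (k > 0L) char_at(M, k - 1L) else char_at(C, core - 1L)
    ins <- .draw_micro_ins(f$micro_ins_len, f$origin, P, decoy, lib, gc,
                           not_first = char_at(C, 0L), not_last = right_nb)
  }
  ref <- paste0(P, M, C, M, Sp)
  carrier <- paste0(P, M, ins, Sp)
  s <- flank; e <- flank + del_len
  L <- nchar(ref)
  carrier_map <- list(
    list(ref_start = 0, ref_end = s + k, strand = "+", seq = NULL),
    if (nzchar(ins)) list(ref_start = NA, ref_end = NA, strand = "*",
                          seq = ins),
    list(ref_start = e + k, ref_end = L, strand = "+", seq = NULL))
  carrier_map <- Filter(Negate(is.null), carrier_map)
  snp_pos <- integer()
  if (f$n_mh_snps > 0L && k >= 18L) {
    offs <- sort(sample(seq(0L, k - 9L, by = 9L), f$n_mh_snps))
    for (o in offs) {
      old <- char_at(carrier, s + o)
      carrier <- set_char(carrier, s + o, diff_base(old))
    }
    snp_pos <- s + offs
  }
  list(ref = ref, carrier = carrier, outgroup = ref,
       ref_map = .ref_map(L), carrier_map = carrier_map,
       truth = list(sv_type = "deletion", sv_len = del_len,
                    sv_span = c(s, e), mh_region = c(s, s + k),
                    tsd_region = NULL, snp_pos = snp_pos,
                    micro_ins_seq = ins))
}

## -- ancestral insertion: ref = P T S, carrier = P T ins T S[d:] ---------
.build_ai <- function(f, config, lib, flank, gc) {
  t <- f$tsd_len; d <- f$micro_del_len
  ## the inserted element must outsize any micro-deletion at its junction
  body_len <- as.integer(round(runif(1, 150, 800))) + d
  src <- lib[[sample(c("LINE1", "ERV"), 1L)]]
  o <- sample.int(nchar(src) - body_len - 1L, 1L) - 1L
  body <- substr0(src, o, o + body_len)
  run <- switch(f$poly_tail,
                polyA_tail = , polyT_head = sample(10:25, 1L),
                truncated = sample(4:7, 1L), 0L)
  ## the element body must not extend the homopolymer run it abuts, or a
  ## truncated/absent tail would read as a full one
  ins <- if (f$poly_tail == "polyT_head") {
    body <- set_char(body, 0L, diff_base("T"))
    paste0(strrep("T", run), body)
  } else {                                # polyA_tail / truncated / absent
    body <- set_char(body, body_len - 1L, diff_base("A"))
    paste0(body, strrep("A", run))
  }
  li <- nchar(ins)
  P <- random_dna(flank, gc); S <- random_dna(flank + 300L, gc)
  Tt <- random_dna(t, gc)
  ## boundary forcing
  S <- set_char(S, 0L, diff_base(char_at(ins, 0L)))
  end_char <- char_at(ins, li - 1L)
  if (d == 0L) {
    if (t > 0L) P <- set_char(P, flank - 1L, diff_base(end_char,
                                                       char_at(S, 0L)))
    else P <- set_char(P, flank - 1L, diff_base(end_char, char_at(S, 0L)))
  } else {
    if (t > 0L) S <- set_char(S, d - 1L, diff_base(char_at(Tt, t - 1L)))
    else S <- set_char(S, d - 1L, diff_base(end_char))
    P <- set_char(P, flank - 1L, diff_base(end_char, char_at(S, d)))
  }
  ref <- paste0(P, Tt, S)
  carrier <- paste0(P, Tt, ins, Tt, substr0(S, d, nchar(S)))
  L <- nchar(ref)
  carrier_map <- Filter(Negate(is.null), list(
    list(ref_start = 0, ref_end = flank + t, strand = "+", seq = NULL),
    list(ref_start = NA, ref_end = NA, strand = "*", seq = ins),
    if (t > 0L) list(ref_start = flank, ref_end = flank + t, strand = "+",
                     seq = NULL),
    list(ref_start = flank + t + d, ref_end = L, strand = "+", seq = NULL)))
  snp_pos <- integer()
  if (f$n_tsd_snps > 0L && t >= 10L) {
    o <- sample.int(t - 8L, 1L) - 1L
    old <- char_at(carrier, flank + o)
    carrier <- set_char(carrier, flank + o, diff_base(old))
    snp_pos <- flank + o
  }
  list(ref = ref, carrier = carrier, outgroup = ref,
       ref_map = .ref_map(L), carrier_map = carrier_map,
       truth = list(sv_type = "insertion", sv_len = li,
                    sv_span = c(flank + t, flank + t + max(1, d)),
                    mh_region = NULL, tsd_region = c(flank, flank + t),
                    snp_pos = snp_pos, ins_seq = ins, tsd_seq = Tt))
}

## -- inversion: ref = P C S, carrier = P ins rc(C[d:]) S -----------------
.build_inv <- function(f, config, flank, gc) {
  d <- f$micro_del_len
  core_len <- as.integer(round(runif(1, 300, 800)))
  core_len <- max(core_len, d + 60L)
  P <- random_dna(flank, gc); S <- random_dna(flank, gc)
  C <- random_dna(core_len, gc)
  ins <- ""
  if (f$micro_ins_len > 0L)
    ins <- random_dna(f$micro_ins_len, gc)
  ## boundary forcing
  if (nzchar(ins)) {
    if (nchar(ins) == 1L) {
      ins <- diff_base(char_at(C, 0L),
                       if (d > 0L) revcomp(char_at(C, d - 1L)))
    } else {
      ins <- set_char(ins, 0L, diff_base(char_at(C, 0L)))
      if (d > 0L)
        ins <- set_char(ins, nchar(ins) - 1L,
                        diff_base(revcomp(char_at(C, d - 1L))))
    }
  } else {
    ## rc(C)[0] = comp(C_last) must not equal C[0]
    C <- set_char(C, core_len - 1L, diff_base(revcomp(char_at(C, 0L))))
  }
  ## LCS stop: comp(C[d]) != C_last
  C <- set_char(C, d, diff_base(revcomp(char_at(C, core_len - 1L))))
  ref <- paste0(P, C, S)
  carrier <- paste0(P, ins, revcomp(substr0(C, d, core_len)), S)
  L <- nchar(ref)
  carrier_map <- Filter(Negate(is.null), list(
    list(ref_start = 0, ref_end = flank, strand = "+", seq = NULL),
    if (nzchar(ins)) list(ref_start = NA, ref_end = NA, strand = "*",
                          seq = ins),
    list(ref_start = flank + d, ref_end = flank + core_len, strand = "-",
         seq = NULL),
    list(ref_start = flank + core_len, ref_end = L, strand = "+",
         seq = NULL)))
  list(ref = ref, carrier = carrier, outgroup = ref,
       ref_map = .ref_map(L), carrier_map = carrier_map,
       truth = list(sv_type = "inversion", sv_len = core_len,
                    sv_span = c(flank, flank + core_len),
                    mh_region = NULL, tsd_region = NULL,
                    snp_pos = integer(), micro_ins_seq = ins))
}

## -- gain (tandem duplication): ref = P U S, carrier = P U x U S ---------
.build_gain <- function(f, config, flank, gc) {
  u_len <- as.integer(round(runif(1, 150, 400)))
  P <- random_dna(flank, gc); S <- random_dna(flank, gc)
  U <- random_dna(u_len, gc)
  x <- if (f$micro_ins_len > 0L) random_dna(f$micro_ins_len, gc) else ""
  ## boundary forcing
  if (nzchar(x)) {
    if (nchar(x) == 1L) {
      x <- diff_base(char_at(S, 0L), char_at(P, flank - 1L))
    } else {
      x <- set_char(x, 0L, diff_base(char_at(S, 0L)))
      x <- set_char(x, nchar(x) - 1L, diff_base(char_at(P, flank - 1L)))
    }
  } else {
    U <- set_char(U, 0L, diff_base(char_at(S, 0L)))
    U <- set_char(U, u_len - 1L, diff_base(char_at(P, flank - 1L)))
  }
  ref <- paste0(P, U, S)
  carrier <- paste0(P, U, x, U, S)
  L <- nchar(ref)
  carrier_map <- Filter(Negate(is.null), list(
    list(ref_start = 0, ref_end = flank + u_len, strand = "+", seq = NULL),
    if (nzchar(x)) list(ref_start = NA, ref_end = NA, strand = "*",
                        seq = x),
    list(ref_start = flank, ref_end = flank + u_len, strand = "+",
         seq = NULL),
    list(ref_start = flank + u_len, ref_end = L, strand = "+", seq = NULL)))
  list(ref = ref, carrier = carrier, outgroup = ref,
       ref_map = .ref_map(L), carrier_map = carrier_map,
       truth = list(sv_type = "gain", sv_len = u_len,
                    sv_span = c(flank, flank + u_len),
                    mh_region = NULL, tsd_region = NULL,
                    snp_pos = integer(), micro_ins_seq = x))
}
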