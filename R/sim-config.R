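#' Breakpoint micro-feature frequencies by ancestry class
#'
#' Default per-class probabilities of junction micro-events, matching the
#' published Sanger survey of 4,176 breakpoints at 261 simple SV loci in 8
#' strains.  Each class gives the probability of no micro-event, a
#' micro-deletion, a micro-insertion, or both, together with the size bin
#' sampled uniformly when the event occurs.  Open upper bins default to the
#' largest observed sizes (107 bp for micro-insertions, 289 bp for
#' micro-deletions).
#'
#' @return A named list (classes `ancestral_insertion`, `ancestral_deletion`,
#'   `inversion`, `gain`) of data.frames with columns `feature`
#'   (`none`/`micro_del`/`micro_ins`/`both`), `lo`, `hi` (size bin, bp) and
#'   `prob`.
#' @export
breakpoint_feature_frequencies <- function() {
  bin <- function(feature, lo, hi, prob)
    data.frame(feature = feature, lo = lo, hi = hi, prob = prob,
               stringsAsFactors = FALSE)
  norm <- function(d) { d$prob <- d$prob / sum(d$prob); d }
  list(
    ## insertion variants: micro-deletion = missing reference bases
    ancestral_insertion = norm(rbind(
      bin("none", 0, 0, 0.848),
      bin("micro_del", 1, 34, 0.143),
      bin("micro_del", 201, 289, 0.010))),
    ## deletion variants: micro-insertion = extra junction sequence
    ancestral_deletion = norm(rbind(
      bin("none", 0, 0, 0.732),
      bin("micro_ins", 1, 10, 0.197),
      bin("micro_ins", 11, 50, 0.056),
      bin("micro_ins", 52, 107, 0.014))),
    ## inversions: two thirds micro-deletion, one third both
    inversion = norm(rbind(
      bin("micro_del", 1, 34, 0.667),
      bin("both", 11, 50, 0.167),
      bin("both", 52, 107, 0.167))),
    gain = norm(rbind(
      bin("none", 0, 0, 0.875),
      bin("micro_ins", 1, 10, 0.125)))
  )
}

#' Simulation configuration
#'
#' All tunable parameters of the synthetic-data generator.  Library insert
#' size is not reported for the source sequencing data, so the defaults
#' (3 kb mean, 300 bp SD, 100 bp reads, 30x depth) are package assumptions
#' chosen so that the insert-size-dependent behaviour of the
#' inversion-with-deletions signature is exercisable around the insert
#' size.
#'
#' @param seed Integer seed controlling all randomness.
#' @param chromosome_lengths Named numeric vector of chromosome lengths.
#' @param gc_fraction Expected G+C base fraction of random sequence.
#' @param repeat_library Named character vector of repeat consensus
#'   sequences (LINE/SINE/ERV-like); NULL generates a default toy library.
#' @param repeat_divergence Per-base substitution rate applied to planted
#'   repeat copies.
#' @param insert_mean,insert_sd Fragment (insert) size distribution, bp.
#' @param read_length Read length, bp.
#' @param depth Mean haploid coverage.
#' @param n_strains Number of strains in the panel.
#' @param strain_order Strain names; `reference_strain()` must be included
#'   and is always simulated without the variant.
#' @param cohort_design Named integer vector: loci per ancestry class for
#'   [simulate_cohort()].  Default is the 261-locus study design
#'   (105 ancestral insertions, 142 ancestral deletions, 6 inversions,
#'   8 gains).
#' @param feature_freqs Output of [breakpoint_feature_frequencies()].
#' @param mh_prob Probability that a deletion-class junction carries
#'   micro-homology (default 0.5: about half of complex non-retrotransposon
#'   SVs show 3-25 bp micro-homology).
#' @param mh_range Micro-homology length range, bp.
#' @param snp_mh_prob Probability that an ancestral deletion carries SNPs
#'   inside its micro-homology co-segregating with the SV (default 0.045).
#' @param snp_tsd_prob Probability that an ancestral insertion carries a
#'   SNP inside its target-site duplication (default 0.16).
#' @param tsd_range TSD length range for retrotransposon insertions, bp.
#' @param tsd_absent_prob Fraction of retrotransposon insertions integrated
#'   without TSD and with truncated/absent poly(A) (default 0.15,
#'   the DNA-lesion/repair integration route).
#' @param origin_probs Probabilities of micro-insertion origin classes
#'   (intra-chromosomal gain, inter-chromosomal gain, retrotransposon
#'   fragment); the three observed routes are sampled uniformly by default.
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(seed = 1L,
                       chromosome_lengths = c(chr19 = 200000),
                       gc_fraction = 0.42,
                       repeat_library = NULL,
                       repeat_divergence = 0.02,
                       insert_mean = 3000,
                       insert_sd = 300,
                       read_length = 100,
                       depth = 30,
                       n_strains = 8L,
                       strain_order = classical_strains(),
                       cohort_design = c(ancestral_insertion = 105,
                                         ancestral_deletion = 142,
                                         inversion = 6, gain = 8),
                       feature_freqs = breakpoint_feature_frequencies(),
                       mh_prob = 0.5,
                       mh_range = c(3, 25),
                       snp_mh_prob = 0.045,
                       snp_tsd_prob = 0.16,
                       tsd_range = c(5, 20),
                       tsd_absent_prob = 0.15,
                       origin_probs = c(intra_chromosomal_gain = 1/3,
                                        inter_chromosomal_gain = 1/3,
                                        retrotransposon = 1/3)) {
  if (insert_mean <= 2 * read_length)
    stop("config error: insert_mean must exceed 2 * read_length")
  if (depth <= 0) stop("config error: depth must be positive")
  if (n_strains != length(strain_order))
    stop("config error: n_strains must match strain_order")
  cfg <- list(seed = as.integer(seed),
              chromosome_lengths = chromosome_lengths,
              gc_fraction = gc_fraction,
              repeat_library = repeat_library,
              repeat_divergence = repeat_divergence,
              insert_mean = insert_mean, insert_sd = insert_sd,
              read_length = read_length, depth = depth,
              n_strains = as.integer(n_strains),
              strain_order = strain_order,
              cohort_design = cohort_design,
              feature_freqs = feature_freqs,
              mh_prob = mh_prob, mh_range = mh_range,
              snp_mh_prob = snp_mh_prob, snp_tsd_prob = snp_tsd_prob,
              tsd_range = tsd_range, tsd_absent_prob = tsd_absent_prob,
              origin_probs = origin_probs)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  chromosomes:", paste(sprintf("%s (%s bp)",
                                      names(x$chromosome_lengths),
                                      x$chromosome_lengths),
                              collapse = ", "), "\n")
  cat(sprintf("  insert %s +/- %s bp, reads %s bp, depth %sx, %d strains\n",
              x$insert_mean, x$insert_sd, x$read_length, x$depth,
              x$n_strains))
  invisible(x)
}

#' Default toy repeat library
#'
#' One LINE-like (6 kb), one SINE-like (300 bp plus A-rich tail) and one
#' ERV-like (1.2 kb) consensus of random sequence at the canonical element
#' sizes.  Real mouse repeat consensus sequences are deliberately not
#' shipped; the library exists to exercise repeat-aware logic, not to
#' model real elements.
#'
#' @param gc Expected G+C fraction.
#' @return Named character vector of consensus sequences.
#' @export
default_repeat_library <- function(gc = 0.42) {
  line <- random_dna(6000, gc)
  sine <- paste0(random_dna(300, gc), strrep("A", 20))
  erv <- random_dna(1200, gc)
  c(LINE1 = line, SINE_B1 = sine, ERV = erv)
}
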