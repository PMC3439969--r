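#' Simulate a breakpoint-sequencing cohort
#'
#' Generates the full study-design cohort: for each ancestry class the
#' configured number of loci is built (counts are fixed, not sampled),
#' each with per-strain assembled alleles carrying micro-features drawn
#' from the class frequency tables, an outgroup allele, and a strain
#' distribution pattern.  Every locus contributes two breakpoints per
#' strain to the sequencing manifest (261 loci x 8 strains x 2 junctions =
#' 4,176 entries under the default design).  Deterministic for a fixed
#' `config$seed`.
#'
#' @param config A [sim_config()]; `config$cohort_design` gives loci per
#'   class.
#' @param out_dir Optional directory: writes per-locus multi-FASTA
#'   (`loci/<id>.fa`, records named `<id>|<strain>`), `truth.bed`,
#'   `truth.vcf`, `sdp.tsv` and `manifest.tsv`, plus per-strain SAM when
#'   `reads = TRUE`.
#' @param reads Also simulate read pairs over every locus contig (uses
#'   3 kb flanks so fragments fit); off by default since breakpoint
#'   analysis works from the assembled sequences.
#' @param flank Flank length per locus, bp (forced to 3000 when
#'   `reads = TRUE`).
#' @return List of class `sv_cohort`: `loci` (list of `bp_locus`),
#'   `truth` (data.frame), `manifest` (data.frame, one row per
#'   locus/strain/junction), `sdp_table`, `genome` (named character:
#'   locus contigs plus a decoy chromosome), `config`.
#' @export
simulate_cohort <- function(config, out_dir = NULL, reads = FALSE,
                            flank = 500L) {
  set.seed(config$seed)
  if (reads)
    flank <- max(flank, config$insert_mean + 6 * config$insert_sd + 1000L)
  lib <- config$repeat_library
  if (is.null(lib)) lib <- default_repeat_library(config$gc_fraction)
  config$repeat_library <- lib
  decoy <- random_dna(4000L, config$gc_fraction)
  design <- config$cohort_design
  loci <- list()
  for (cls in names(design)) {
    n <- design[[cls]]
    if (n < 1) next
    tag <- toupper(substr(gsub("ancestral_", "", cls), 1, 3))
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", tag, i)
      loci[[id]] <- build_locus_alleles(id, cls, config, decoy = decoy,
                                        flank = flank)
    }
  }
  truth <- do.call(rbind, lapply(loci, function(l) {
    tr <- l$truth
    data.frame(id = l$id, class = l$class, sv_type = tr$sv_type,
               start = tr$sv_span[1], end = tr$sv_span[2],
               sv_len = tr$sv_len,
               micro_ins_len = tr$micro_ins_len,
               micro_del_len = tr$micro_del_len,
               mh_len = tr$mh_len, tsd_len = tr$tsd_len,
               poly_tail = tr$poly_tail,
               snp_in_mh = tr$n_mh_snps > 0,
               snp_in_tsd = tr$n_tsd_snps > 0,
               origin = tr$origin,
               sdp = format(l$sdp),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  manifest <- do.call(rbind, lapply(loci, function(l)
    expand.grid(locus = l$id, strain = config$strain_order,
                junction = c("bp1", "bp2"), stringsAsFactors = FALSE)))
  rownames(manifest) <- NULL
  sdp_table <- data.frame(locus = vapply(loci, `[[`, "", "id"),
                          sdp = vapply(loci, function(l) format(l$sdp), ""),
                          stringsAsFactors = FALSE)
  rownames(sdp_table) <- NULL
  genome <- c(setNames(vapply(loci, `[[`, "", "ref_allele"),
                       names(loci)),
              decoy = decoy)
  cohort <- structure(list(loci = loci, truth = truth, manifest = manifest,
                           sdp_table = sdp_table, genome = genome,
                           config = config),
                      class = "sv_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir, reads = reads)
  cohort
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat("<sv_cohort>", length(x$loci), "loci,",
      nrow(x$manifest), "manifest entries\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Analyze every locus of a cohort
#'
#' @param cohort An `sv_cohort`.
#' @return List of `breakpoint_report`s, one per locus.
#' @export
analyze_cohort <- function(cohort) {
  lapply(cohort$loci, analyze_locus,
         genome = cohort$genome,
         repeat_library = cohort$config$repeat_library,
         strain_order = cohort$config$strain_order)
}

#' Write cohort files
#'
#' @param cohort An `sv_cohort`.
#' @param out_dir Output directory (created if missing).
#' @param reads Also write per-strain SAM alignments.
#' @return Invisibly, the output directory.
#' @export
write_cohort <- function(cohort, out_dir, reads = FALSE) {
  dir.create(file.path(out_dir, "loci"), recursive = TRUE,
             showWarnings = FALSE)
  for (l in cohort$loci) {
    seqs <- c(setNames(l$ref_allele, paste0(l$id, "|reference")),
              setNames(unname(l$strain_alleles),
                       paste0(l$id, "|", names(l$strain_alleles))),
              setNames(l$outgroup_allele, paste0(l$id, "|outgroup")))
    writeXStringSet(DNAStringSet(seqs),
                    file.path(out_dir, "loci", paste0(l$id, ".fa")))
  }
  tr <- cohort$truth
  ## BED: 0-based half-open, extra columns sv_type/class/sdp
  write.table(data.frame(tr$id, tr$start, tr$end, tr$id, tr$sv_type,
                         tr$class, tr$sdp),
              file.path(out_dir, "truth.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_truth_vcf(cohort, file.path(out_dir, "truth.vcf"))
  write.table(cohort$sdp_table, file.path(out_dir, "sdp.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (reads) {
    cfg <- cohort$config
    for (strain in cfg$strain_order) {
      pairs <- do.call(rbind, lapply(cohort$loci, function(l) {
        hap <- .assemble_hap(l$ref_allele, l$maps[[strain]], l$id)
        simulate_read_pairs(hap, cfg, strain = strain)
      }))
      write_sam(pairs,
                setNames(nchar(cohort$genome), names(cohort$genome)),
                file.path(out_dir, paste0(gsub("/", "_", strain), ".sam")),
                read_length = cfg$read_length)
    }
  }
  invisible(out_dir)
}
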