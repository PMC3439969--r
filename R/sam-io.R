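## File-format frontiers: SAM alignment records, truth VCF, locus FASTA.
## Internal coordinates are 0-based half-open and converted here; SAM and
## VCF are 1-based.

#' Write read-pair records as SAM
#'
#' @param pairs Read-pair data.frame from [simulate_read_pairs()].
#' @param contig_lengths Named vector of reference contig lengths.
#' @param path Output file.
#' @param read_length Read length (for the CIGAR).
#' @return Invisibly, the path.
#' @export
write_sam <- function(pairs, contig_lengths, path, read_length = 100L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  writeLines("@PG\tID:svarch\tPN:svarch", con)
  if (!nrow(pairs)) return(invisible(path))
  cigar <- paste0(read_length, "M")
  line <- function(qname, flag, rname, pos, cigar_, rnext, pnext, tlen, seq) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*", qname, flag,
            rname, pos, ifelse(flag %% 8L >= 4L, 0L, 60L), cigar_, rnext,
            pnext, tlen, seq)
  }
  p <- pairs
  f1 <- 1L + 64L + ifelse(p$mapped1, 0L, 4L) + ifelse(p$mapped2, 0L, 8L) +
    ifelse(p$mapped1 & p$strand1 == "-", 16L, 0L) +
    ifelse(p$mapped2 & p$strand2 == "-", 32L, 0L)
  f2 <- 1L + 128L + ifelse(p$mapped2, 0L, 4L) + ifelse(p$mapped1, 0L, 8L) +
    ifelse(p$mapped2 & p$strand2 == "-", 16L, 0L) +
    ifelse(p$mapped1 & p$strand1 == "-", 32L, 0L)
  pos1 <- ifelse(p$mapped1, p$pos1, ifelse(p$mapped2, p$pos2, 0)) + 1L
  pos2 <- ifelse(p$mapped2, p$pos2, ifelse(p$mapped1, p$pos1, 0)) + 1L
  tlen <- ifelse(is.na(p$inferred_insert), 0L, as.integer(p$inferred_insert))
  seq1 <- ifelse(is.na(p$seq1), "*", p$seq1)
  seq2 <- ifelse(is.na(p$seq2), "*", p$seq2)
  writeLines(line(p$pair_id, f1, p$chrom, as.integer(pos1),
                  ifelse(p$mapped1, cigar, "*"), "=", as.integer(pos2),
                  tlen, seq1), con)
  writeLines(line(p$pair_id, f2, p$chrom, as.integer(pos2),
                  ifelse(p$mapped2, cigar, "*"), "=", as.integer(pos1),
                  -tlen, seq2), con)
  invisible(path)
}

#' Read a SAM/BAM file back into read-pair records
#'
#' Uses Rsamtools; SAM input is converted to BAM in a temporary directory.
#'
#' @param path SAM or BAM file.
#' @return A read-pair data.frame in the [simulate_read_pairs()] layout.
#' @export
read_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_sam() requires the Rsamtools package")
  bam <- path
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "seq")))[[1L]]
  fl <- b$flag
  first <- bitwAnd(fl, 64L) > 0L
  rl <- max(b$qwidth, na.rm = TRUE)
  df <- data.frame(qname = b$qname, first = first,
                   chrom = as.character(b$rname),
                   pos = b$pos - 1L,
                   mapped = bitwAnd(fl, 4L) == 0L,
                   strand = ifelse(bitwAnd(fl, 16L) > 0L, "-", "+"),
                   seq = as.character(b$seq),
                   stringsAsFactors = FALSE)
  d1 <- df[first, ]; d2 <- df[!first, ]
  d2 <- d2[match(d1$qname, d2$qname), ]
  pos1 <- ifelse(d1$mapped, d1$pos, NA_real_)
  pos2 <- ifelse(d2$mapped, d2$pos, NA_real_)
  both <- d1$mapped & d2$mapped
  insert <- ifelse(both, pmax(pos1 + rl, pos2 + rl) - pmin(pos1, pos2),
                   NA_real_)
  data.frame(pair_id = d1$qname, strain = NA_character_,
             chrom = ifelse(d1$mapped, d1$chrom, d2$chrom),
             pos1 = pos1, end1 = pos1 + rl,
             strand1 = ifelse(d1$mapped, d1$strand, "*"),
             mapped1 = d1$mapped,
             pos2 = pos2, end2 = pos2 + rl,
             strand2 = ifelse(d2$mapped, d2$strand, "*"),
             mapped2 = d2$mapped,
             frag_hap_start = NA_real_, frag_len = NA_real_,
             seq1 = ifelse(d1$mapped, NA_character_, d1$seq),
             seq2 = ifelse(d2$mapped, NA_character_, d2$seq),
             inferred_insert = insert, stringsAsFactors = FALSE)
}

#' Write a cohort truth set as VCF 4.2 symbolic records
#'
#' @param cohort An `sv_cohort`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_truth_vcf <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=svarch",
               sprintf("##contig=<ID=%s,length=%d>", names(cohort$genome),
                       nchar(cohort$genome)),
               "##ALT=<ID=DEL,Description=\"Deletion\">",
               "##ALT=<ID=INS,Description=\"Insertion\">",
               "##ALT=<ID=INV,Description=\"Inversion\">",
               "##ALT=<ID=DUP,Description=\"Duplication\">",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length\">",
               "##INFO=<ID=COMPLEXITY,Number=1,Type=String,Description=\"Adjudication\">",
               "##INFO=<ID=MHLEN,Number=1,Type=Integer,Description=\"Micro-homology length\">",
               "##INFO=<ID=MICROINS,Number=1,Type=Integer,Description=\"Micro-insertion length\">",
               "##INFO=<ID=MICRODEL,Number=1,Type=Integer,Description=\"Micro-deletion length\">",
               "##INFO=<ID=TSD,Number=1,Type=Integer,Description=\"TSD length\">",
               "##INFO=<ID=SDP,Number=1,Type=String,Description=\"Strain distribution pattern\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")),
             con)
  tr <- cohort$truth
  sym <- c(deletion = "<DEL>", insertion = "<INS>", inversion = "<INV>",
           gain = "<DUP>")
  svt <- c(deletion = "DEL", insertion = "INS", inversion = "INV",
           gain = "DUP")
  for (i in seq_len(nrow(tr))) {
    ref_base <- substr0(cohort$genome[[tr$id[i]]], tr$start[i],
                        tr$start[i] + 1L)
    info <- sprintf(
      "SVTYPE=%s;END=%d;SVLEN=%d;MHLEN=%d;MICROINS=%d;MICRODEL=%d;TSD=%d;SDP=%s",
      svt[[tr$sv_type[i]]], as.integer(tr$end[i]),
      as.integer(tr$sv_len[i]), as.integer(tr$mh_len[i]),
      as.integer(tr$micro_ins_len[i]), as.integer(tr$micro_del_len[i]),
      as.integer(tr$tsd_len[i]), tr$sdp[i])
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s", tr$id[i],
                       tr$start[i] + 1L, tr$id[i], ref_base,
                       sym[[tr$sv_type[i]]], info), con)
  }
  invisible(path)
}

#' Read a per-locus multi-FASTA into the analyzer's locus layout
#'
#' Records must be named `<locus>|<strain>`, with strains `reference` and
#' `outgroup` holding the reference and outgroup alleles.
#'
#' @param path FASTA file.
#' @return A list usable by [analyze_locus()].
#' @export
read_locus_set <- function(path) {
  x <- readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  strains <- vapply(parts, `[`, "", 2L)
  id <- ids[1L]
  seqs <- setNames(as.character(x), strains)
  list(id = id,
       ref_allele = unname(seqs[["reference"]]),
       strain_alleles = seqs[!strains %in% c("reference", "outgroup")],
       outgroup_allele = if ("outgroup" %in% strains)
         unname(seqs[["outgroup"]]) else NULL)
}
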