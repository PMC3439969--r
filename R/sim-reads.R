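#' Simulate paired-end read records from a haplotype
#'
#' Fragments are drawn with normally distributed lengths at the configured
#' depth and both reads are placed on the reference through the coordinate
#' map: no read mapper is run, so placements are exact.  Reads falling
#' (by majority) inside novel inserted sequence are emitted unmapped
#' (orphaned mates); reads inside inverted segments have their strand
#' flipped; reads spanning a junction are placed by the side holding the
#' majority of their bases (minority bases are implicitly soft-masked).
#'
#' @param hap Output of [apply_sv()] (list `haplotype`, `map`, `chrom`).
#' @param config A [sim_config()].
#' @param strain Strain label stored with each pair.
#' @param keep_unmapped_seq Store the sequence of unmapped reads (needed to
#'   match orphan mates against the repeat library).
#' @return A data.frame, one row per pair: `pair_id`, `strain`, `chrom`,
#'   `pos1`, `end1`, `strand1`, `mapped1`, `pos2`, `end2`, `strand2`,
#'   `mapped2`, `frag_hap_start`, `frag_len`, `seq1`, `seq2` (sequence only
#'   for unmapped reads), `inferred_insert` (NA when a mate is unmapped).
#'   Positions are 0-based half-open on the reference.
#' @export
simulate_read_pairs <- function(hap, config, strain = "sample",
                                keep_unmapped_seq = TRUE) {
  rl <- config$read_length
  hl <- nchar(hap$haplotype)
  if (hl <= config$insert_mean + 6 * config$insert_sd)
    stop("haplotype shorter than insert_mean + 6*insert_sd")
  n <- round(config$depth * hl / (2 * rl))
  if (n < 1) {
    warning("depth yields no fragments; returning empty output")
    return(.empty_pairs())
  }
  fl <- round(rnorm(n, config$insert_mean, config$insert_sd))
  fl <- pmax(fl, 2 * rl + 10)
  fl <- pmin(fl, hl)
  fs <- floor(runif(n, 0, hl - fl + 1))
  ## read 1 = leftmost on the haplotype (forward), read 2 reverse
  r1 <- .map_reads(fs, fs + rl, "+", hap$map)
  r2 <- .map_reads(fs + fl - rl, fs + fl, "-", hap$map)
  seq1 <- seq2 <- rep(NA_character_, n)
  if (keep_unmapped_seq) {
    u1 <- which(!r1$mapped)
    if (length(u1))
      seq1[u1] <- substring(hap$haplotype, fs[u1] + 1, fs[u1] + rl)
    u2 <- which(!r2$mapped)
    if (length(u2))
      seq2[u2] <- substring(hap$haplotype, fs[u2] + fl[u2] - rl + 1,
                            fs[u2] + fl[u2])
  }
  both <- r1$mapped & r2$mapped
  lo <- pmin(r1$pos, r2$pos)
  hi <- pmax(r1$pos + rl, r2$pos + rl)
  insert <- ifelse(both, hi - lo, NA_real_)
  out <- data.frame(
    pair_id = paste0(strain, "_p", seq_len(n)),
    strain = strain, chrom = hap$chrom,
    pos1 = r1$pos, end1 = r1$pos + rl, strand1 = r1$strand,
    mapped1 = r1$mapped,
    pos2 = r2$pos, end2 = r2$pos + rl, strand2 = r2$strand,
    mapped2 = r2$mapped,
    frag_hap_start = fs, frag_len = fl,
    seq1 = seq1, seq2 = seq2,
    inferred_insert = insert,
    stringsAsFactors = FALSE)
  ## fragments entirely inside novel sequence leave no usable record
  out[out$mapped1 | out$mapped2, , drop = FALSE]
}

.empty_pairs <- function() {
  data.frame(pair_id = character(), strain = character(), chrom = character(),
             pos1 = numeric(), end1 = numeric(), strand1 = character(),
             mapped1 = logical(), pos2 = numeric(), end2 = numeric(),
             strand2 = character(), mapped2 = logical(),
             frag_hap_start = numeric(), frag_len = numeric(),
             seq1 = character(), seq2 = character(),
             inferred_insert = numeric(), stringsAsFactors = FALSE)
}

## place reads [a, b) on the reference through the coordinate map, by
## majority overlap when a read straddles segment junctions
.map_reads <- function(a, b, hap_orient, map) {
  k <- nrow(map)
  n <- length(a)
  ov <- matrix(0, n, k)
  for (j in seq_len(k))
    ov[, j] <- pmax(0, pmin(b, map$hap_end[j]) - pmax(a, map$hap_start[j]))
  best <- max.col(ov, ties.method = "first")
  seg_strand <- map$strand[best]
  hs <- map$hap_start[best]
  rs <- map$ref_start[best]; re <- map$ref_end[best]
  pos <- ifelse(seg_strand == "-", re - (b - hs), rs + (a - hs))
  mapped <- seg_strand != "*"
  strand <- ifelse(seg_strand == "-",
                   ifelse(hap_orient == "+", "-", "+"),
                   hap_orient)
  strand[!mapped] <- "*"
  pos[!mapped] <- NA_real_
  list(pos = pos, strand = strand, mapped = mapped)
}
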