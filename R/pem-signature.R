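#' Classifier tuning parameters
#'
#' The published pattern catalog was built by visual inspection and states
#' no numeric thresholds, so every cutoff is exposed here.
#'
#' @param min_support Minimum read pairs per discordant/orphan cluster.
#' @param k_sd Insert-size discordance threshold, in SDs of the library.
#' @param merge_distance Single-linkage merge distance for clusters
#'   (defaults to the insert mean at classification time when NULL).
#' @param window Depth profile window, bp.
#' @param zero_frac,loss_frac,gain_frac Depth-state thresholds relative to
#'   the locus-flank median `m`: zero below `zero_frac*m`, loss below
#'   `loss_frac*m`, gain above `gain_frac*m`.
#' @param min_state_run Minimum consecutive windows for a zero/loss depth
#'   state to be believed (smooths Poisson window noise).
#' @param min_gain_run Minimum consecutive windows for a gain state; gains
#'   sit closer to the noise floor than zero-depth calls, so they need a
#'   longer run.
#' @param nml_gap Maximum normal-copy gap between two deletions called as
#'   one Del+Nml+Del locus, bp.
#' @param large_del Length above which a deletion is called "large"
#'   (questionable pattern Q4), bp.
#' @param repeat_frac Minimum fraction of a deleted span covered by repeat
#'   annotation to call the repeat flavour (H2/Q3).
#' @param linked_max Maximum source-to-copy separation for a linked (vs
#'   dispersed) gain, bp.
#' @param small_gain_max Maximum total gain-state width still considered a
#'   "small" gain (the defining property of the linked-gain patterns
#'   Q5/Q9), bp.
#' @param exon_pad Padding around annotated exons when testing retrogene
#'   exon-skipping geometry, bp.
#' @param vntr_frac Minimum fraction of the deletion-like span inside an
#'   annotated tandem-repeat array for the VNTR patterns.
#' @param microsat_unit Maximum repeat unit length called a microsatellite
#'   (pattern Q1 rather than Q7), bp.
#' @return A list of parameters.
#' @export
classifier_params <- function(min_support = 3L, k_sd = 4, merge_distance = NULL,
                              window = 200L, zero_frac = 0.1, loss_frac = 0.6,
                              gain_frac = 1.4, min_state_run = 2L, min_gain_run = 3L,
                              nml_gap = 500, large_del = 1e5,
                              repeat_frac = 0.5, linked_max = 5000,
                              small_gain_max = 2000, exon_pad = 300,
                              vntr_frac = 0.5, microsat_unit = 6L) {
  as.list(environment())
}

#' Windowed read depth and copy-number states over a locus
#'
#' Counts read coverage in fixed windows across the locus, normalizes by
#' the median depth of the flanking windows, and segments the locus into
#' states `zero` / `loss` / `normal` / `gain` with change points at state
#' transitions.  Non-normal states shorter than `min_state_run` windows are
#' smoothed back to normal.
#'
#' @param pairs Read-pair data.frame from [simulate_read_pairs()] (or
#'   [read_sam()]).
#' @param locus A [gint()] delimiting the analyzed region.
#' @param params [classifier_params()].
#' @return List of class `depth_profile`: `windows` (data.frame `start`,
#'   `end`, `depth`, `state`), `states` (run-length segments: `start`,
#'   `end`, `state`), `flank_median`.
#' @export
compute_depth_profile <- function(pairs, locus, params = classifier_params()) {
  w <- params$window
  stopifnot(inherits(locus, "gint"), w >= 1)
  reads <- .mapped_reads(pairs, locus$chrom)
  nwin <- max(1L, floor((locus$end - locus$start) / w))
  ws <- locus$start + (seq_len(nwin) - 1L) * w
  we <- ws + w
  ## coverage of the locus by mapped reads (1-based IRanges internally)
  ir <- IRanges(pmax(1, reads$pos + 1 - locus$start),
                pmax(0, reads$end - locus$start))
  ir <- ir[IRanges::width(ir) > 0 & IRanges::start(ir) <=
             (locus$end - locus$start)]
  cov <- coverage(ir, width = locus$end - locus$start)
  v <- Views(cov, IRanges(ws - locus$start + 1, we - locus$start))
  depth <- viewMeans(v)
  nf <- max(3L, ceiling(0.1 * nwin))
  flank_idx <- unique(c(seq_len(min(nf, nwin)),
                        seq(max(1L, nwin - nf + 1L), nwin)))
  m <- median(depth[flank_idx])
  if (m <= 0) stop("cannot-normalize: zero coverage in locus flanks")
  state <- rep("normal", nwin)
  state[depth > params$gain_frac * m] <- "gain"
  state[depth < params$loss_frac * m] <- "loss"
  state[depth < params$zero_frac * m] <- "zero"
  ## smooth: short non-normal runs revert to normal (gains need a longer
  ## run than zero/loss, being closer to the noise floor)
  r <- rle(state)
  r$values[r$values %in% c("zero", "loss") &
             r$lengths < params$min_state_run] <- "normal"
  r$values[r$values == "gain" & r$lengths < params$min_gain_run] <- "normal"
  state <- inverse.rle(r)
  r <- rle(state)
  seg_end_idx <- cumsum(r$lengths)
  seg_start_idx <- seg_end_idx - r$lengths + 1L
  states <- data.frame(start = ws[seg_start_idx], end = we[seg_end_idx],
                       state = r$values, stringsAsFactors = FALSE)
  structure(list(windows = data.frame(start = ws, end = we, depth = depth,
                                      state = state),
                 states = states, flank_median = m),
            class = "depth_profile")
}

.mapped_reads <- function(pairs, chrom = NULL) {
  keep <- if (is.null(chrom)) TRUE else pairs$chrom == chrom
  p <- pairs[keep, , drop = FALSE]
  r1 <- data.frame(pos = p$pos1, end = p$end1, strand = p$strand1,
                   mapped = p$mapped1)
  r2 <- data.frame(pos = p$pos2, end = p$end2, strand = p$strand2,
                   mapped = p$mapped2)
  out <- rbind(r1, r2)
  out[out$mapped & !is.na(out$pos), , drop = FALSE]
}

#' Cluster discordant and orphaned read pairs
#'
#' A pair is discordant when its inferred insert deviates from the library
#' mean by more than `k_sd` SDs, when its orientation is not
#' forward-reverse (FR), or when one mate is unmapped (an orphan).
#' Discordant pairs are grouped by orientation class (`long_FR`,
#' `short_FR`, `FF`, `RR`, `RF`) and clustered by single linkage on both
#' mate footprints; orphan mates are clustered on the mapped mate.
#' Clusters with fewer than `min_support` pairs are discarded.
#'
#' @param pairs Read-pair data.frame.
#' @param insert_stats List or vector with `mean` and `sd` of the library
#'   insert size.
#' @param params [classifier_params()].
#' @return List of class `pem_clusters` with data.frames `clusters`
#'   (`class`, `left_start`, `left_end`, `right_start`, `right_end`,
#'   `support`, `median_insert`) and `orphans` (`start`, `end`, `support`),
#'   plus `orphan_seqs` (list of unmapped mate sequences per orphan
#'   cluster).
#' @export
cluster_discordant_pairs <- function(pairs, insert_stats,
                                     params = classifier_params()) {
  mu <- insert_stats[["mean"]]; sd <- insert_stats[["sd"]]
  md <- params$merge_distance
  if (is.null(md)) md <- mu
  p <- pairs
  both <- p$mapped1 & p$mapped2
  ## orient pairs left/right on the reference
  swap <- both & (p$pos2 < p$pos1)
  lpos <- ifelse(swap, p$pos2, p$pos1); lend <- ifelse(swap, p$end2, p$end1)
  lstr <- ifelse(swap, p$strand2, p$strand1)
  rpos <- ifelse(swap, p$pos1, p$pos2); rend <- ifelse(swap, p$end1, p$end2)
  rstr <- ifelse(swap, p$strand1, p$strand2)
  orient <- rep(NA_character_, nrow(p))
  orient[both & lstr == "+" & rstr == "-"] <- "FR"
  orient[both & lstr == "+" & rstr == "+"] <- "FF"
  orient[both & lstr == "-" & rstr == "-"] <- "RR"
  orient[both & lstr == "-" & rstr == "+"] <- "RF"
  insert <- rend - lpos
  cls <- orient
  cls[both & orient == "FR" & insert > mu + params$k_sd * sd] <- "long_FR"
  cls[both & orient == "FR" & insert < mu - params$k_sd * sd] <- "short_FR"
  disc <- both & cls != "FR"
  clusters <- list()
  for (cl in c("long_FR", "short_FR", "FF", "RR", "RF")) {
    i <- which(disc & cls == cl)
    if (!length(i)) next
    o <- i[order(lpos[i])]
    brk <- cumsum(c(0, diff(lpos[o]) > md | abs(diff(rpos[o])) > md))
    for (g in split(o, brk)) {
      if (length(g) < params$min_support) next
      clusters[[length(clusters) + 1L]] <- data.frame(
        class = cl, left_start = min(lpos[g]), left_end = max(lend[g]),
        right_start = min(rpos[g]), right_end = max(rend[g]),
        support = length(g), median_insert = median(insert[g]),
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(class = character(), left_start = numeric(),
               left_end = numeric(), right_start = numeric(),
               right_end = numeric(), support = integer(),
               median_insert = numeric(), stringsAsFactors = FALSE)
  ## orphans: one mapped mate, one unmapped
  orphan_i <- which(xor(p$mapped1, p$mapped2))
  opos <- ifelse(p$mapped1[orphan_i], p$pos1[orphan_i], p$pos2[orphan_i])
  oend <- ifelse(p$mapped1[orphan_i], p$end1[orphan_i], p$end2[orphan_i])
  oseq <- ifelse(p$mapped1[orphan_i], p$seq2[orphan_i], p$seq1[orphan_i])
  orphans <- data.frame(start = numeric(), end = numeric(),
                        support = integer(), stringsAsFactors = FALSE)
  orphan_seqs <- list()
  if (length(orphan_i)) {
    o <- order(opos)
    brk <- cumsum(c(0, diff(opos[o]) > md))
    for (g in split(o, brk)) {
      if (length(g) < params$min_support) next
      orphans <- rbind(orphans, data.frame(
        start = min(opos[g]), end = max(oend[g]), support = length(g)))
      orphan_seqs[[nrow(orphans)]] <- oseq[g][!is.na(oseq[g])]
    }
  }
  structure(list(clusters = clusters, orphans = orphans,
                 orphan_seqs = orphan_seqs),
            class = "pem_clusters")
}

#' Extract the full PEM signature of a locus
#'
#' Bundles the depth profile and the discordant/orphan clusters into the
#' per-locus evidence object consumed by [classify_pattern()].
#'
#' @inheritParams compute_depth_profile
#' @inheritParams cluster_discordant_pairs
#' @return List of class `pem_signature`.
#' @export
pem_signature <- function(pairs, locus, insert_stats,
                          params = classifier_params()) {
  keep <- (pairs$mapped1 & !is.na(pairs$pos1) & pairs$end1 > locus$start - 1e6 &
             pairs$pos1 < locus$end + 1e6) |
          (pairs$mapped2 & !is.na(pairs$pos2) & pairs$end2 > locus$start - 1e6 &
             pairs$pos2 < locus$end + 1e6)
  p <- pairs[keep & pairs$chrom == locus$chrom, , drop = FALSE]
  depth <- compute_depth_profile(p, locus, params)
  clust <- cluster_discordant_pairs(p, insert_stats, params)
  structure(list(locus = locus, depth = depth, clusters = clust),
            class = "pem_signature")
}
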