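#' Generate a synthetic reference genome with annotation
#'
#' Builds random chromosomes at the configured GC content, plants copies of
#' the repeat library (at the configured per-copy divergence) and toy
#' multi-exon genes, and returns the sequences together with BED-style
#' annotation tables.  Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @param repeats_per_mb Planted repeat copies per megabase per chromosome.
#' @param genes_per_chrom Toy multi-exon genes per chromosome.
#' @return An object of class `sv_reference`: list with `genome` (named
#'   character vector of chromosome sequences), `repeat_library` and
#'   `annotation` (list of data.frames `repeats`, `genes`, `exons`, all
#'   0-based half-open).
#' @export
generate_reference <- function(config, repeats_per_mb = 30,
                               genes_per_chrom = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$chromosome_lengths < 10 * config$insert_mean))
    stop("config error: chromosome shorter than 10 * insert_mean")
  set.seed(config$seed)
  lib <- config$repeat_library
  if (is.null(lib)) lib <- default_repeat_library(config$gc_fraction)

  genome <- character()
  repeats <- genes <- exons <- list()
  for (chrom in names(config$chromosome_lengths)) {
    L <- config$chromosome_lengths[[chrom]]
    seq <- random_dna(L, config$gc_fraction)
    ## plant repeat copies at non-overlapping positions (overwrite in place
    ## so chromosome length and downstream coordinates stay fixed)
    n_rep <- max(0L, round(repeats_per_mb * L / 1e6))
    occupied <- IRanges()
    for (k in seq_len(n_rep)) {
      fam <- sample(names(lib), 1L)
      cons <- lib[[fam]]
      w <- nchar(cons)
      if (w + 200 > L) next
      pos <- .free_position(L, w, occupied, tries = 50L)
      if (is.na(pos)) next
      copy <- mutate_seq(cons, config$repeat_divergence)
      substr(seq, pos + 1, pos + w) <- copy
      occupied <- c(occupied, IRanges(pos + 1, pos + w))
      repeats[[length(repeats) + 1L]] <-
        data.frame(chrom = chrom, start = pos, end = pos + w, family = fam,
                   stringsAsFactors = FALSE)
    }
    ## toy genes: 3-5 exons of 150-400 bp separated by 1-3 kb introns
    for (k in seq_len(genes_per_chrom)) {
      n_ex <- sample(3:5, 1L)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(1000:3000, n_ex - 1L, replace = TRUE)
      g_len <- sum(ex_len) + sum(in_len)
      pos <- .free_position(L, g_len, occupied, tries = 50L)
      if (is.na(pos)) next
      occupied <- c(occupied, IRanges(pos + 1, pos + g_len))
      gid <- sprintf("%s_gene%d", chrom, k)
      at <- pos
      for (ei in seq_len(n_ex)) {
        exons[[length(exons) + 1L]] <-
          data.frame(chrom = chrom, start = at, end = at + ex_len[ei],
                     gene_id = gid, exon = ei, stringsAsFactors = FALSE)
        at <- at + ex_len[ei] + if (ei < n_ex) in_len[ei] else 0L
      }
      genes[[length(genes) + 1L]] <-
        data.frame(chrom = chrom, start = pos, end = pos + g_len,
                   gene_id = gid, n_exons = n_ex, stringsAsFactors = FALSE)
    }
    genome[[chrom]] <- seq
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  structure(list(
    genome = genome,
    repeat_library = lib,
    annotation = list(
      repeats = bind(repeats, data.frame(chrom = character(),
                                         start = numeric(), end = numeric(),
                                         family = character())),
      genes = bind(genes, data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), gene_id = character(),
                                     n_exons = integer())),
      exons = bind(exons, data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), gene_id = character(),
                                     exon = integer())))),
    class = "sv_reference")
}

## substitute a fraction `rate` of positions with a different base
mutate_seq <- function(x, rate) {
  if (rate <= 0 || !nzchar(x)) return(x)
  n <- nchar(x)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(x)
  pos <- sample.int(n, k)
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  ch[pos] <- vapply(ch[pos],
                    function(b) sample(setdiff(.BASES, b), 1L), "")
  paste(ch, collapse = "")
}

## pick a start for a width-w feature avoiding `occupied` (1-based IRanges);
## returns 0-based start or NA
.free_position <- function(L, w, occupied, tries = 50L) {
  for (t in seq_len(tries)) {
    pos <- sample.int(L - w - 200L, 1L) + 100L   # keep off chromosome ends
    cand <- IRanges(pos + 1, pos + w)
    if (!length(occupied) ||
        !any(overlapsAny(cand, occupied))) return(pos)
  }
  NA_integer_
}

#' @export
print.sv_reference <- function(x, ...) {
  cat("<sv_reference>", length(x$genome), "chromosome(s),",
      nrow(x$annotation$repeats), "repeat copies,",
      nrow(x$annotation$genes), "toy gene(s)\n")
  invisible(x)
}
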