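## Per-code single-locus simulation used by the classifier round-trip
## machinery: each architecture code gets a dedicated mini-chromosome with
## exactly the genomic context it needs (a repeat copy to delete, a VNTR
## array, a multi-exon gene for retrogenes, ...).

#' Simulate one locus carrying a given architecture
#'
#' Builds a dedicated reference chromosome, constructs the event with
#' sizes drawn from code-appropriate ranges, applies it, simulates read
#' pairs and returns everything needed to classify the locus.
#'
#' @param code Architecture code from [sv_codes()].
#' @param config A [sim_config()]; `chromosome_lengths` is ignored (the
#'   locus chooses its own chromosome size).
#' @param carrier Simulate the SV-carrying haplotype (TRUE) or the
#'   reference haplotype (FALSE, e.g. for non-carrier strains).
#' @param strain Strain label for the read records.
#' @return List with `code`, `event`, `genome` (named character),
#'   `annotation`, `hap`, `pairs`, `locus` ([gint()] classification
#'   window).
#' @export
simulate_locus <- function(code, config, carrier = TRUE, strain = "sample") {
  gc <- config$gc_fraction
  mu <- config$insert_mean
  lib <- config$repeat_library
  if (is.null(lib)) lib <- default_repeat_library(gc)
  L <- switch(code,
              LARGE_DEL = 360000,
              DISPERSED_GAIN = , RETROGENE_FALSE_DEL = ,
              RETROGENE_FALSE_INV = 120000,
              60000)
  chrom <- "sim"
  seq <- random_dna(L, gc)
  ann <- list(repeats = NULL, exons = NULL, vntr = NULL,
              repeat_library = lib)
  c0 <- round(L / 2)
  ui <- function(a, b) round(runif(1, a, b))
  ev <- NULL

  if (code %in% c("DEL_UNIQUE", "LARGE_DEL")) {
    len <- if (code == "LARGE_DEL") ui(110000, 140000) else ui(2000, 6000)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + len)
  } else if (code == "DEL_REPEAT") {
    cons <- lib[["LINE1"]]
    w <- nchar(cons)
    substr(seq, c0 + 1, c0 + w) <- mutate_seq(cons, config$repeat_divergence)
    ann$repeats <- data.frame(chrom = chrom, start = c0, end = c0 + w,
                              family = "LINE1")
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + w)
  } else if (code == "DEL_NML_DEL") {
    d1 <- ui(1500, 3000); gap <- ui(450, 500); d2 <- ui(1500, 3000)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + d1 + gap + d2,
                        gap_start = c0 + d1, gap_end = c0 + d1 + gap)
  } else if (code == "INV") {
    len <- ui(6000, 12000)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + len)
  } else if (code == "DEL_INV") {
    d1 <- ui(600, 1200); iv <- ui(2000, 10000); d2 <- ui(600, 1200)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + d1 + iv + d2,
                        inv_start = c0 + d1, inv_end = c0 + d1 + iv)
  } else if (code == "INS_UNIQUE") {
    ev <- make_sv_event(code, chrom, insertion_point = c0,
                        inserted_sequence = random_dna(ui(800, 3000), gc))
  } else if (code == "INS_REPEAT") {
    fam <- sample(c("SINE_B1", "LINE1"), 1L)
    insseq <- if (fam == "SINE_B1") lib[[fam]] else {
      o <- ui(0, nchar(lib[[fam]]) - 2000)
      substr0(lib[[fam]], o, o + ui(800, 2000))
    }
    ev <- make_sv_event(code, chrom, insertion_point = c0,
                        inserted_sequence = mutate_seq(insseq, 0.02))
  } else if (code == "TANDEM_DUP") {
    len <- ui(2800, 6000)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + len)
  } else if (code == "INV_TANDEM_DUP") {
    len <- ui(2800, 6000)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + len)
  } else if (code == "DISPERSED_GAIN") {
    len <- ui(2800, 5000)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + len,
                        target = c0 + len + ui(25000, 35000))
  } else if (code == "SV_IN_GAIN") {
    len <- ui(5000, 6500)
    m1 <- c0 + ui(800, 1200)
    m2 <- m1 + ui(1500, 2500)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + len,
                        del_in_copy = c(m1, m2))
  } else if (code == "VNTR") {
    u <- if (runif(1) < 0.5) sample(3:6, 1L) else ui(15, 60)
    unit <- random_dna(u, gc)
    n_ref <- max(ceiling(3500 / u), 4L)
    array <- strrep(unit, n_ref)
    substr(seq, c0 + 1, c0 + nchar(array)) <- array
    ann$vntr <- data.frame(chrom = chrom, start = c0,
                           end = c0 + u * n_ref, unit_len = u)
    k_del <- max(ceiling(1800 / u), 1L)  # units lost by the carrier
    ev <- make_sv_event(code, chrom, start = c0, unit_len = u,
                        n_ref = n_ref, n_alt = n_ref - k_del)
  } else if (code == "DEL_INS") {
    len <- ui(1500, 3000)
    ins_len <- round(mu + 6 * config$insert_sd + ui(0, 1000))
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + len,
                        inserted_sequence = random_dna(ins_len, gc))
  } else if (code == "INV_INS") {
    len <- ui(2000, 8000)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + len,
                        inserted_sequence = random_dna(ui(400, 700), gc))
  } else if (code == "LINKED_GAIN") {
    len <- ui(800, 1400)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + len,
                        target = c0 + len + ui(2000, 3000))
  } else if (code == "INV_LINKED_GAIN") {
    len <- ui(800, 1400)
    ev <- make_sv_event(code, chrom, start = c0, end = c0 + len,
                        target = c0 + len + ui(2000, 3000))
  } else if (code %in% c("RETROGENE_FALSE_DEL", "RETROGENE_FALSE_INV")) {
    ## the processed copy must outsize the insert so that read pairs fall
    ## entirely within it and span exon-exon junctions
    n_ex <- sample(3:4, 1L)
    ex_len <- round(runif(n_ex, 900, 1500))
    in_len <- round(runif(n_ex - 1L, 1800, 3000))
    at <- c0
    ex <- data.frame(start = numeric(n_ex), end = numeric(n_ex))
    for (i in seq_len(n_ex)) {
      ex$start[i] <- at; ex$end[i] <- at + ex_len[i]
      at <- at + ex_len[i] + if (i < n_ex) in_len[i] else 0
    }
    ann$exons <- data.frame(chrom = chrom, start = ex$start, end = ex$end,
                            gene_id = "gene1", exon = seq_len(n_ex))
    ev <- make_sv_event(code, chrom, exons = ex,
                        target = max(ex$end) + ui(25000, 30000))
  } else stop("unsupported architecture code: ", code)

  genome <- setNames(seq, chrom)
  hap <- if (carrier) apply_sv(genome, ev) else
    list(haplotype = seq,
         map = data.frame(hap_start = 0, hap_end = nchar(seq),
                          ref_start = 0, ref_end = nchar(seq),
                          strand = "+"),
         chrom = chrom)
  pairs <- simulate_read_pairs(hap, config, strain = strain)
  margin <- 4 * mu
  iv <- ev$ref_interval
  locus <- gint(chrom, max(0, iv$start - margin),
                min(L, iv$end + margin))
  list(code = code, event = ev, genome = genome, annotation = ann,
       hap = hap, pairs = pairs, locus = locus)
}
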