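cfg <- test_config(seed = 11L, chromosome_lengths = c(chr1 = 60000))

test_that("generate_reference is deterministic and annotates its plants", {
  r1 <- generate_reference(cfg, repeats_per_mb = 40)
  r2 <- generate_reference(cfg, repeats_per_mb = 40)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$annotation$repeats, r2$annotation$repeats)
  ## planted repeat copies match their consensus at the configured
  ## divergence
  rep1 <- r1$annotation$repeats[1, ]
  copy <- substr(r1$genome[[rep1$chrom]], rep1$start + 1, rep1$end)
  cons <- r1$repeat_library[[rep1$family]]
  mism <- mean(strsplit(copy, "")[[1]] != strsplit(cons, "")[[1]])
  expect_lt(mism, 0.06)
  expect_gt(nrow(r1$annotation$exons), 0)
  expect_error(generate_reference(test_config(
    chromosome_lengths = c(tiny = 1000))), "config error")
})

test_that("GC content tracks the configured fraction", {
  cfg5 <- test_config(seed = 2L, chromosome_lengths = c(c = 1e6),
                      gc_fraction = 0.5)
  r <- generate_reference(cfg5, repeats_per_mb = 0, genes_per_chrom = 0)
  gc <- sum(strsplit(r$genome[["c"]], "")[[1]] %in% c("G", "C")) / 1e6
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e6))
})

test_that("apply_sv handles the worked deletion+insertion arithmetic", {
  r <- generate_reference(cfg)
  L <- nchar(r$genome[["chr1"]])
  ev <- make_sv_event("DEL_INS", "chr1", start = 20000, end = 20547,
                      inserted_sequence = random_dna(34))
  h <- apply_sv(r, ev)
  expect_equal(nchar(h$haplotype), L - 547 + 34)
})

test_that("inversion application is an involution", {
  r <- generate_reference(cfg)
  ev <- make_sv_event("INV", "chr1", start = 10000, end = 18000)
  h1 <- apply_sv(r, ev)
  expect_identical(substr0(h1$haplotype, 10000, 18000),
                   revcomp(substr0(r$genome[["chr1"]], 10000, 18000)))
  h2 <- apply_sv(setNames(h1$haplotype, "chr1"), ev)
  expect_identical(h2$haplotype, r$genome[["chr1"]])
})

test_that("DEL_INV haplotypes match string-level manual construction", {
  set.seed(3)
  for (i in 1:20) {
    x <- random_dna(5000)
    s <- sample(1000:2000, 1)
    d1 <- sample(100:400, 1); iv <- sample(300:1500, 1)
    d2 <- sample(100:400, 1)
    ev <- make_sv_event("DEL_INV", "c", start = s, end = s + d1 + iv + d2,
                        inv_start = s + d1, inv_end = s + d1 + iv)
    h <- apply_sv(c(c = x), ev)
    manual <- paste0(substr0(x, 0, s),
                     revcomp(substr0(x, s + d1, s + d1 + iv)),
                     substr0(x, s + d1 + iv + d2, nchar(x)))
    expect_identical(h$haplotype, manual)
  }
})

test_that("every architecture code yields a consistent coordinate map", {
  cfg2 <- test_config()
  set.seed(21)
  for (code in sv_codes()) {
    sl <- simulate_locus(code, cfg2)
    m <- sl$event
    map <- sl$hap$map
    ## map tiles the haplotype
    expect_equal(map$hap_start[1], 0)
    expect_equal(map$hap_end[nrow(map)], nchar(sl$hap$haplotype))
    expect_true(all(map$hap_start[-1] == map$hap_end[-nrow(map)]))
    ## mapped segments reproduce reference sequence (strand-aware)
    for (j in seq_len(nrow(map))) {
      if (map$strand[j] == "*") next
      piece <- substr0(sl$hap$haplotype, map$hap_start[j], map$hap_end[j])
      refp <- substr0(sl$genome[[1]], map$ref_start[j], map$ref_end[j])
      expect_identical(piece,
                       if (map$strand[j] == "-") revcomp(refp) else refp)
    }
  }
})

test_that("read pairs from an unrearranged genome are concordant", {
  r <- generate_reference(cfg, repeats_per_mb = 0, genes_per_chrom = 0)
  hap <- list(haplotype = r$genome[["chr1"]],
              map = data.frame(hap_start = 0, hap_end = 60000,
                               ref_start = 0, ref_end = 60000,
                               strand = "+"),
              chrom = "chr1")
  set.seed(5)
  pr <- simulate_read_pairs(hap, cfg)
  fr <- with(pr, (strand1 == "+" & strand2 == "-" & pos1 <= pos2) |
                   (strand2 == "+" & strand1 == "-" & pos2 <= pos1))
  good <- fr & abs(pr$inferred_insert - cfg$insert_mean) <
    4 * cfg$insert_sd
  expect_gt(mean(good), 0.99)
})

test_that("a deletion inflates spanning inserts by its length", {
  set.seed(6)
  sl <- simulate_locus("DEL_UNIQUE", test_config())
  del_len <- interval_length(sl$event$ref_interval)
  s <- sl$event$ref_interval$start
  span <- with(sl$pairs, mapped1 & mapped2 &
                 pmin(pos1, pos2) < s - 150 & pmax(end1, end2) > s + 150)
  expect_gt(sum(span), 10)
  expect_equal(median(sl$pairs$inferred_insert[span]),
               cfg$insert_mean + del_len, tolerance = 0.1)
})

test_that("an inversion+insertion leaves orphans at one junction only", {
  set.seed(8)
  cfg2 <- test_config()
  sl <- simulate_locus("INV_INS", cfg2)
  cl <- cluster_discordant_pairs(sl$pairs, insert_stats(cfg2))
  expect_gte(nrow(cl$orphans), 1)
  ## all orphan clusters sit at the insertion junction (right end of the
  ## inverted span), not at the other breakpoint
  iv <- sl$event$ref_interval
  expect_true(all(abs((cl$orphans$start + cl$orphans$end) / 2 - iv$end) <
                    cfg2$insert_mean))
})

test_that("breakpoint feature draws reproduce the class frequencies", {
  cfg2 <- test_config()
  set.seed(31)
  draws <- replicate(10000, {
    plant_breakpoint_features(list(params = list()), cfg2,
                              "ancestral_deletion")$params$features
  }, simplify = FALSE)
  none <- mean(vapply(draws, function(f) f$micro_ins_len == 0, TRUE))
  expect_lt(abs(none - 0.732), 0.015)  # ~3 binomial SDs at n = 10,000
  sizes <- vapply(draws, function(f) f$micro_ins_len, 0L)
  expect_true(all(sizes[sizes > 0] >= 1 & sizes[sizes > 0] <= 107))
  ## micro-homology defaults: about half of junctions, 3-25 bp
  mh <- vapply(draws, function(f) f$mh_len, 0L)
  expect_lt(abs(mean(mh > 0) - (0.045 + (1 - 0.045) * 0.5)), 0.02)
  expect_true(all(mh <= 25))
})

test_that("a planted TSD is duplicated on both insertion flanks", {
  cfg2 <- test_config()
  set.seed(12)
  f <- list(class = "ancestral_insertion", feature = "none",
            micro_ins_len = 0L, micro_del_len = 0L, mh_len = 0L,
            n_mh_snps = 0L, tsd_len = 15L, poly_tail = "polyA_tail",
            n_tsd_snps = 0L, origin = "retrotransposon")
  l <- build_locus_alleles("L1", "ancestral_insertion", cfg2, features = f)
  carrier <- l$strain_alleles[[which(l$sdp$presence == 1)[1]]]
  tsd <- l$truth$tsd_seq
  expect_equal(nchar(tsd), 15L)
  ## carrier = ...TSD [element + polyA] TSD..., so two copies; ref has one
  expect_equal(lengths(regmatches(carrier,
                                  gregexpr(tsd, carrier, fixed = TRUE))), 2L)
  expect_equal(lengths(regmatches(l$ref_allele,
                                  gregexpr(tsd, l$ref_allele,
                                           fixed = TRUE))), 1L)
  expect_match(l$truth$ins_seq, "AAAAAAAA")
})

test_that("micro-homology of zero leaves a blunt junction", {
  cfg2 <- test_config()
  set.seed(13)
  f <- list(class = "ancestral_deletion", feature = "none",
            micro_ins_len = 0L, micro_del_len = 0L, mh_len = 0L,
            n_mh_snps = 0L, tsd_len = 0L, poly_tail = "not_applicable",
            n_tsd_snps = 0L, origin = "none")
  l <- build_locus_alleles("L1", "ancestral_deletion", cfg2, features = f)
  mh <- find_microhomology(l$ref_allele,
                           gint("L1", l$truth$sv_span[1],
                                l$truth$sv_span[2]))
  expect_equal(mh$length, 0L)
  expect_equal(mh$sequence, "")
})

test_that("cohort composition is fixed, deterministic, and truth-consistent", {
  small <- test_config(seed = 77L,
                       cohort_design = c(ancestral_insertion = 5,
                                         ancestral_deletion = 7,
                                         inversion = 2, gain = 1))
  co1 <- simulate_cohort(small)
  co2 <- simulate_cohort(small)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$genome, co2$genome)
  expect_equal(as.vector(table(co1$truth$class)[c("ancestral_insertion",
                                                  "ancestral_deletion",
                                                  "inversion", "gain")]),
               c(5L, 7L, 2L, 1L))
  expect_equal(nrow(co1$manifest), 15 * 8 * 2)
  ## truth consistency: rebuilding the carrier allele from the reference
  ## and the truth record reproduces the emitted allele (deletion class)
  for (id in co1$truth$id[co1$truth$class == "ancestral_deletion"]) {
    l <- co1$loci[[id]]
    tr <- co1$truth[co1$truth$id == id, ]
    k <- tr$mh_len
    rebuilt <- paste0(substr0(l$ref_allele, 0, tr$start + k),
                      l$truth$micro_ins_seq,
                      substr0(l$ref_allele, tr$end + k,
                              nchar(l$ref_allele)))
    carrier <- l$strain_alleles[[which(l$sdp$presence == 1)[1]]]
    if (tr$snp_in_mh) next  # carrier additionally holds planted SNPs
    expect_identical(carrier, rebuilt)
  }
  ## zero-count designs produce valid empty outputs
  empty <- test_config(cohort_design = c(ancestral_deletion = 0))
  co0 <- simulate_cohort(empty)
  expect_equal(length(co0$loci), 0L)
})

test_that("cohort files round-trip through FASTA and SAM", {
  tiny <- test_config(seed = 5L,
                      cohort_design = c(ancestral_deletion = 2,
                                        ancestral_insertion = 1))
  dir <- tempfile("cohort")
  co <- simulate_cohort(tiny, out_dir = dir, reads = TRUE)
  fa <- list.files(file.path(dir, "loci"), full.names = TRUE)
  expect_length(fa, 3L)
  l <- read_locus_set(fa[1])
  orig <- co$loci[[l$id]]
  expect_identical(l$ref_allele, orig$ref_allele)
  expect_identical(l$strain_alleles, orig$strain_alleles)
  expect_identical(l$outgroup_allele, orig$outgroup_allele)
  sams <- list.files(dir, pattern = "\\.sam$", full.names = TRUE)
  expect_length(sams, 8L)
  pr <- read_sam(sams[1])
  expect_gt(nrow(pr), 100)
  expect_true(all(xor(pr$mapped1, pr$mapped2) | (pr$mapped1 & pr$mapped2)))
  expect_true(file.exists(file.path(dir, "truth.vcf")))
  vcf <- readLines(file.path(dir, "truth.vcf"))
  expect_equal(sum(!startsWith(vcf, "#")), 3L)
})
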