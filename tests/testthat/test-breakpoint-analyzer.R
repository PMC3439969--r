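cfg <- test_config()

test_that("breakpoints are located where alleles stop and start aligning", {
  set.seed(201)
  ## 547 bp deletion whose junction carries a 34 bp novel insertion: the
  ## non-carrier middle is the deleted 547 bp, the carrier middle the
  ## 34 bp insertion
  P <- random_dna(300); S <- random_dna(300)
  del <- random_dna(547); ins <- random_dna(34)
  while (substr(ins, 1, 1) == substr(del, 1, 1)) ins <- random_dna(34)
  while (substr(ins, 34, 34) == substr(del, 547, 547))
    ins <- paste0(substr(ins, 1, 33), sample(c("A","C","G","T"), 1))
  while (substr(del, 1, 1) == substr(S, 1, 1)) del <- random_dna(547)
  ref <- paste0(P, del, S)
  carrier <- paste0(P, ins, S)
  dec <- locate_breakpoints(carrier, ref)
  expect_equal(dec$bp1, 300)
  expect_equal(nchar(dec$noncarrier_middle), 547)
  expect_equal(nchar(dec$carrier_middle), 34)
  ev <- call_micro_events(dec, reference = ref)
  expect_equal(ev$sv_type, "deletion")
  expect_equal(ev$sv_len, 547)
  expect_identical(ev$micro_insertion, ins)
})

test_that("identical alleles report no variant; bad flanks refuse to anchor", {
  x <- random_dna(400)
  dec <- locate_breakpoints(x, x)
  expect_true(dec$no_variant)
  expect_equal(call_micro_events(dec)$sv_type, "none")
  expect_error(locate_breakpoints(random_dna(400), random_dna(400)),
               "unanchored-locus")
})

test_that("planted breakpoints are recovered exactly on clean sequence", {
  set.seed(202)
  for (i in 1:100) {
    flank <- sample(100:400, 1)
    del_len <- sample(50:600, 1)
    P <- random_dna(flank); S <- random_dna(flank)
    D <- random_dna(del_len)
    if (substr(D, 1, 1) == substr(S, 1, 1))
      D <- paste0(setdiff(c("A","C","G","T"), substr(S, 1, 1))[1],
                  substr(D, 2, del_len))
    if (substr(D, del_len, del_len) == substr(P, flank, flank))
      D <- paste0(substr(D, 1, del_len - 1),
                  setdiff(c("A","C","G","T"), substr(P, flank, flank))[1])
    dec <- locate_breakpoints(paste0(P, S), paste0(P, D, S))
    expect_equal(dec$bp1, flank)
    expect_equal(dec$bp2_noncarrier, flank + del_len)
  }
})

test_that("find_microhomology equals the exhaustive placement oracle", {
  set.seed(203)
  for (i in 1:150) {
    x <- random_dna(30)
    w <- sample(1:8, 1)
    s <- sample(0:(30 - w), 1)
    mh <- suppressWarnings(find_microhomology(x, c(s, s + w)))
    eq <- equivalent_placements(x, s, s + w)
    expect_equal(mh$length, length(eq) - 1L,
                 label = sprintf("%s del [%d,%d)", x, s, s + w))
    ## left-most placement consistency
    expect_equal(mh$leftmost_start, min(eq))
  }
})

test_that("micro-homology detection recovers a planted duplicated motif", {
  set.seed(204)
  loc <- make_mh_locus("GATTACA", 60)
  mh <- find_microhomology(loc$ref, c(loc$s, loc$e))
  expect_equal(mh$length, 7L)
  expect_equal(mh$sequence, "GATTACA")
})

test_that("TSD and poly-tail detection covers all three configurations", {
  set.seed(205)
  t <- random_dna(12)
  body <- paste0(random_dna(150), strrep("A", 18))
  lf <- paste0(random_dna(50), t)
  rf <- paste0(t, random_dna(50))
  ## (a) TSD outside the called insertion on both flanks
  r <- detect_tsd_polya(body, lf, rf)
  expect_equal(r$tsd, t)
  expect_equal(r$poly_tail, "polyA_tail")
  ## (b) one copy absorbed at the end of the called insertion
  r <- detect_tsd_polya(paste0(body, t), lf, random_dna(50))
  expect_equal(r$tsd, t)
  expect_equal(r$poly_tail, "polyA_tail")
  ## (c) one copy absorbed at the start (right flank forced to diverge
  ## from the body right after the duplication, as real junctions do)
  rest <- random_dna(50)
  while (substr(rest, 1, 1) == substr(body, 1, 1)) rest <- random_dna(50)
  r <- detect_tsd_polya(paste0(t, body), random_dna(50), paste0(t, rest))
  expect_equal(r$tsd, t)
  ## no duplication, no tail
  r <- detect_tsd_polya(random_dna(100), random_dna(50), random_dna(50))
  expect_equal(r$tsd, "")
  expect_equal(r$poly_tail, "absent")
  ## truncated tail and poly(T) head
  r <- detect_tsd_polya(paste0(random_dna(80), "CAAAAA"), lf, rf)
  expect_equal(r$poly_tail, "truncated")
  r <- detect_tsd_polya(paste0(strrep("T", 15), "C", random_dna(80)),
                        random_dna(40), random_dna(40))
  expect_equal(r$poly_tail, "polyT_head")
})

test_that("outgroup comparison polarizes ancestry both ways", {
  set.seed(206)
  P <- random_dna(200); S <- random_dna(200); D <- random_dna(300)
  with_seg <- paste0(P, D, S)
  without <- paste0(P, S)
  ## outgroup carries the segment -> the lacking allele lost it
  expect_equal(infer_ancestry(without, with_seg, with_seg, "deletion"),
               "ancestral_deletion")
  ## outgroup lacks the segment -> the bearing allele gained it
  expect_equal(infer_ancestry(with_seg, without, without, "insertion"),
               "ancestral_insertion")
  expect_equal(infer_ancestry(with_seg, without, without, "inversion"),
               "not_applicable")
  expect_error(infer_ancestry(with_seg, without, NULL), "outgroup")
})

test_that("SNP co-segregation requires all carriers and no non-carriers", {
  set.seed(207)
  loc <- make_mh_locus("GAACTA", 64, flank = 150)
  strains <- classical_strains()
  carrier_mut <- loc$carrier
  substr(carrier_mut, 154, 154) <- "G"   # C -> G at MH offset 3
  pres <- c(1, 1, 1, 1, 0, 1, 0, 1)
  alleles <- setNames(ifelse(pres == 1, carrier_mut, loc$ref), strains)
  res <- test_snp_cosegregation(loc$ref, alleles, sdp(pres),
                                c(loc$s, loc$s + 6))
  expect_true(res$cosegregating)
  expect_equal(res$positions, 153)
  ## partial sharing is not flagged
  alleles2 <- alleles
  alleles2[["A/J"]] <- loc$carrier
  res2 <- test_snp_cosegregation(loc$ref, alleles2, sdp(pres),
                                 c(loc$s, loc$s + 6))
  expect_false(res2$cosegregating)
  ## degenerate designs are not applicable
  res3 <- test_snp_cosegregation(loc$ref, alleles, sdp(rep(1, 8)),
                                 c(loc$s, loc$s + 6))
  expect_true(res3$not_applicable)
})

test_that("micro-insertion origin classification obeys the tie order", {
  set.seed(208)
  lib <- cfg$repeat_library
  genome <- c(chrA = random_dna(5000), chrB = random_dna(5000))
  intra <- substr(genome[["chrA"]], 1001, 1060)
  inter <- substr(genome[["chrB"]], 2001, 2060)
  retro <- substr(lib[["LINE1"]], 501, 560)
  expect_equal(classify_insertion_origin(intra, genome, "chrA", lib),
               "intra_chromosomal_gain")
  expect_equal(classify_insertion_origin(inter, genome, "chrA", lib),
               "inter_chromosomal_gain")
  expect_equal(classify_insertion_origin(retro, genome, "chrA", lib),
               "retrotransposon")
  expect_equal(classify_insertion_origin(random_dna(60), genome, "chrA",
                                         lib), "de_novo")
  expect_equal(classify_insertion_origin("ACGTACG", genome, "chrA", lib),
               "none")
})

test_that("whole-locus analysis round-trips planted architectures", {
  set.seed(209)
  for (cls in c("ancestral_deletion", "ancestral_insertion", "inversion",
                "gain")) {
    for (i in 1:15) {
      l <- build_locus_alleles(sprintf("%s_%d", cls, i), cls, cfg)
      r <- analyze_locus(l, repeat_library = cfg$repeat_library,
                         strain_order = cfg$strain_order)
      tr <- l$truth
      expect_equal(r$sv_type, tr$sv_type, label = cls)
      expect_equal(format(r$sdp), format(l$sdp), label = cls)
      if (cls == "ancestral_deletion") {
        expect_identical(r$architecture$micro_insertion, tr$micro_ins_seq)
        expect_equal(nchar(r$architecture$micro_homology), tr$mh_len)
        expect_equal(c(r$sv_span$start, r$sv_span$end), tr$sv_span)
        expect_equal(r$ancestry, "ancestral_deletion")
      }
      if (cls == "ancestral_insertion") {
        expect_equal(r$architecture$micro_deletion_length, tr$micro_del_len)
        expect_equal(nchar(r$architecture$tsd), tr$tsd_len)
        expect_equal(r$architecture$poly_tail, tr$poly_tail)
        expect_equal(r$ancestry, "ancestral_insertion")
      }
      if (cls == "inversion") {
        expect_equal(nchar(r$architecture$micro_insertion),
                     tr$micro_ins_len)
        expect_equal(r$architecture$micro_deletion_length,
                     tr$micro_del_len)
      }
      if (cls == "gain") expect_equal(r$dup_len, tr$sv_len)
    }
  }
})

test_that("feature summary is column-normalized and order-invariant", {
  set.seed(210)
  co <- simulate_cohort(test_config(
    seed = 17L, cohort_design = c(ancestral_deletion = 20,
                                  ancestral_insertion = 10,
                                  inversion = 3, gain = 2)))
  reps <- analyze_cohort(co)
  sm1 <- summarize_breakpoint_features(reps)
  sm2 <- summarize_breakpoint_features(rev(reps))
  expect_identical(sm1$counts, sm2$counts)
  used <- sm1$n_by_class > 0
  expect_true(all(abs(colSums(sm1$percent[, used, drop = FALSE]) - 100)
                  < 1e-9))
  ## a single clean deletion is 100% "None"
  f0 <- list(class = "ancestral_deletion", feature = "none",
             micro_ins_len = 0L, micro_del_len = 0L, mh_len = 0L,
             n_mh_snps = 0L, tsd_len = 0L, poly_tail = "not_applicable",
             n_tsd_snps = 0L, origin = "none")
  l <- build_locus_alleles("solo", "ancestral_deletion", cfg, features = f0)
  sm <- summarize_breakpoint_features(list(analyze_locus(l)))
  expect_equal(unname(sm$percent["None", "ancestral_deletion"]), 100)
  expect_equal(sm$complex_fraction, 0)
})
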