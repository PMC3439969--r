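cfg <- test_config()
istats <- insert_stats(cfg)

test_that("depth profile segments a homozygous deletion into states", {
  set.seed(101)
  sl <- simulate_locus("DEL_UNIQUE", cfg)
  dp <- compute_depth_profile(sl$pairs, sl$locus)
  iv <- sl$event$ref_interval
  expect_equal(dp$windows$state[1], "normal")
  inside <- dp$windows$start >= iv$start + 200 & dp$windows$end <= iv$end - 200
  expect_true(all(dp$windows$state[inside] == "zero"))
  expect_gt(dp$flank_median, 0.5 * cfg$depth)
  expect_error(compute_depth_profile(sl$pairs[0, ], sl$locus),
               "cannot-normalize")
})

test_that("a tandem duplication doubles depth over the duplicated span", {
  set.seed(102)
  sl <- simulate_locus("TANDEM_DUP", cfg)
  dp <- compute_depth_profile(sl$pairs, sl$locus)
  iv <- sl$event$ref_interval
  inside <- dp$windows$start >= iv$start + 300 &
    dp$windows$end <= iv$end - 300
  ratio <- mean(dp$windows$depth[inside]) / dp$flank_median
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("clusters carry the diagnostic orientation classes", {
  set.seed(103)
  del <- simulate_locus("DEL_UNIQUE", cfg)
  cl <- cluster_discordant_pairs(del$pairs, istats)
  expect_true("long_FR" %in% cl$clusters$class)
  lfr <- cl$clusters[cl$clusters$class == "long_FR", ]
  expect_equal(nrow(lfr), 1L)
  expect_gte(lfr$support, 3)
  inv <- simulate_locus("INV", cfg)
  cli <- cluster_discordant_pairs(inv$pairs, istats)
  expect_true(all(c("FF", "RR") %in% cli$clusters$class))
  ## pure inversion: pairs wholly inside the span stay concordant; only
  ## junction-spanning pairs are discordant
  iv <- inv$event$ref_interval
  p <- inv$pairs
  both_in <- p$mapped1 & p$mapped2 & pmin(p$pos1, p$pos2) > iv$start + 10 &
    pmax(p$end1, p$end2) < iv$end - 10
  conc <- with(p[both_in, ], (strand1 == "+" & strand2 == "-" &
                                pos1 <= pos2) |
                 (strand2 == "+" & strand1 == "-" & pos2 <= pos1))
  expect_gt(mean(conc), 0.99)
})

test_that("each architecture is recovered from its own simulation", {
  ## a fast spot check (3 replicates/code); the 50-replicate version is
  ## the acceptance criterion
  set.seed(104)
  for (code in c("DEL_UNIQUE", "DEL_INV", "INS_UNIQUE", "TANDEM_DUP",
                 "VNTR", "DEL_INS", "LINKED_GAIN", "RETROGENE_FALSE_DEL")) {
    for (r in 1:3) {
      sl <- simulate_locus(code, cfg)
      call <- classify_locus(sl$pairs, sl$locus, sl$annotation, istats)
      expect_false(call$pattern == "no_call", label = code)
      expect_equal(pattern_code(call$pattern), code, label = code)
    }
  }
})

test_that("the complex pattern wins over its simple sub-pattern", {
  ## an inversion with flanking deletions satisfies both the inversion
  ## (H4) and deletion (H1) sub-rules; the call must be the complex H5
  set.seed(105)
  sl <- simulate_locus("DEL_INV", cfg)
  call <- classify_locus(sl$pairs, sl$locus, sl$annotation, istats)
  expect_equal(call$pattern, "H5")
  expect_equal(call$complexity, "complex")
})

test_that("H5 is recognized below and above the insert size", {
  ## small inversion: fragments span the whole event and read as a
  ## deletion; the zero-depth flanks still mark the H5 architecture
  set.seed(106)
  x <- random_dna(60000)
  for (iv_len in c(1200, 9000)) {
    ev <- make_sv_event("DEL_INV", "c", start = 25000,
                        end = 25000 + 800 + iv_len + 800,
                        inv_start = 25800, inv_end = 25800 + iv_len)
    h <- apply_sv(c(c = x), ev)
    pr <- simulate_read_pairs(h, cfg)
    call <- classify_locus(pr, gint("c", 14000, 48000), list(), istats)
    expect_equal(call$pattern, "H5", label = paste("inv", iv_len))
  }
})

test_that("linked gains never show depth loss", {
  set.seed(107)
  sl <- simulate_locus("LINKED_GAIN", cfg)
  sig <- pem_signature(sl$pairs, sl$locus, istats)
  expect_false(any(sig$depth$states$state %in% c("zero", "loss")))
  expect_true("long_FR" %in% sig$clusters$clusters$class)
  call <- classify_pattern(sig, sl$annotation, istats)
  expect_equal(call$pattern, "Q5")
  expect_equal(call$confidence, "questionable")
})

test_that("retrogenes are never called as true deletions or inversions", {
  set.seed(108)
  for (code in c("RETROGENE_FALSE_DEL", "RETROGENE_FALSE_INV")) {
    for (r in 1:3) {
      sl <- simulate_locus(code, cfg)
      call <- classify_locus(sl$pairs, sl$locus, sl$annotation, istats)
      expect_false(call$pattern %in% c("H1", "H2", "H4"), label = code)
      expect_true(call$pattern %in% c("Q6", "Q10"), label = code)
      expect_equal(call$complexity, "false")
    }
  }
})

test_that("a flat locus yields a no-call, not a fabricated pattern", {
  set.seed(109)
  sl <- simulate_locus("DEL_UNIQUE", cfg, carrier = FALSE)
  call <- classify_locus(sl$pairs, sl$locus, sl$annotation, istats)
  expect_equal(call$pattern, "no_call")
  expect_true(is.na(call$code))
})

test_that("correct calls are stable in depth (10x/30x/60x)", {
  set.seed(110)
  for (code in c("DEL_UNIQUE", "INV", "TANDEM_DUP")) {
    sl <- simulate_locus(code, cfg)  # fixes genome + event
    for (depth in c(10, 30, 60)) {
      cfg_d <- cfg
      cfg_d$depth <- depth
      pr <- simulate_read_pairs(sl$hap, cfg_d)
      call <- classify_locus(pr, sl$locus, sl$annotation, istats)
      expect_equal(pattern_code(call$pattern), code,
                   label = sprintf("%s at %dx", code, depth))
    }
  }
})

test_that("SDP inference matches the worked example", {
  mk <- function(p) structure(list(pattern = p), class = "pattern_call")
  ## strains 1-4, 6 and 8 carry the deletion; C57BL/6J (position 5) is
  ## the reference strain and is forced absent
  calls <- setNames(lapply(c("H1", "H1", "H1", "H1", "no_call", "H1",
                             "no_call", "H1"), mk), classical_strains())
  expect_equal(format(infer_sdp(calls)), "11110101")
  expect_equal(format(infer_sdp(setNames(lapply(rep("no_call", 8), mk),
                                         classical_strains()))),
               "00000000")
  expect_error(infer_sdp(calls[1:7]), "incomplete")
})
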