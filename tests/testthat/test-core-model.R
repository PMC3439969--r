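test_that("interval lengths match the printed 1-based inclusive spans", {
  expect_equal(interval_length(from_paper_coords("chr10", 20467348,
                                                 20467894)), 547)
  expect_equal(interval_length(from_paper_coords("chr12", 27040459,
                                                 27040522)), 64)
  expect_equal(interval_length(from_paper_coords("chrX", 100, 100)), 1)
  expect_error(gint("chr1", 10, 10), "invalid interval")
  expect_error(from_paper_coords("chr1", 5, 4), "conversion error")
})

test_that("paper-coordinate conversion is a bijection", {
  set.seed(42)
  for (i in 1:1000) {
    s1 <- sample.int(1e8, 1)
    e1 <- s1 + sample.int(1e5, 1) - 1L
    g <- from_paper_coords("c", s1, e1)
    p <- to_paper_coords(g)
    expect_equal(c(p$start1, p$end1), c(s1, e1))
    expect_equal(interval_length(g), e1 - s1 + 1)
  }
})

test_that("the pattern catalog has 21 entries mapping onto 19 codes", {
  tab <- pem_pattern_table()
  expect_equal(nrow(tab), 21L)
  expect_equal(sum(tab$confidence == "high"), 11L)
  expect_equal(sum(tab$confidence == "questionable"), 10L)
  expect_length(sv_codes(), 19L)
  ## spot checks against the published adjudication column
  expect_equal(pattern_complexity(c("H5", "Q6", "Q7", "H1", "Q2")),
               c("complex", "false", "VNTR", "simple", "complex"))
  expect_equal(pattern_code(c("H1", "Q4", "Q1", "Q7", "Q2", "Q3")),
               c("DEL_UNIQUE", "LARGE_DEL", "VNTR", "VNTR", "DEL_INS",
                 "DEL_INS"))
  expect_equal(sv_complexity("DEL_INV"), "complex")
  expect_equal(sv_complexity("RETROGENE_FALSE_DEL"), "false")
  expect_error(sv_complexity("NOT_A_CODE"), "unknown")
})

test_that("strain distribution patterns format and parse", {
  s <- sdp(c(1, 1, 1, 1, 0, 1, 0, 1))
  expect_equal(format(s), "11110101")
  expect_equal(format(parse_sdp("11110101")), "11110101")
  expect_error(sdp(c(1, 1), classical_strains()), "lengths differ")
  expect_equal(classical_strains()[5], reference_strain())
})

test_that("leftmost_normalize matches the exhaustive placement oracle", {
  set.seed(7)
  for (i in 1:200) {
    k <- sample(1:12, 1)
    core <- sample((k + 5):40, 1)
    loc <- make_mh_locus(random_dna(k), core, flank = 60L)
    genome <- c(chrZ = loc$ref)
    ## report the deletion at a random equivalent placement
    placements <- equivalent_placements(loc$ref, loc$s, loc$e)
    s2 <- sample(placements, 1)
    ev <- sv_event("d", "DEL_UNIQUE", gint("chrZ", s2, s2 + loc$e - loc$s))
    norm <- leftmost_normalize(ev, genome)
    expect_equal(norm$ref_interval$start, min(placements))
    ## sample-sequence preserving and idempotent
    expect_identical(
      apply_deletion_str(loc$ref, norm$ref_interval$start,
                         norm$ref_interval$end),
      apply_deletion_str(loc$ref, s2, s2 + loc$e - loc$s))
    again <- leftmost_normalize(norm, genome)
    expect_equal(again$ref_interval$start, norm$ref_interval$start)
  }
})

test_that("leftmost_normalize leaves blunt junctions and inversions alone", {
  genome <- c(c1 = "ACGTACGGTTCAGCTTAACGGA")
  ev <- sv_event("d", "DEL_UNIQUE", gint("c1", 8, 12))
  mh <- find_microhomology(genome, gint("c1", 8, 12))
  if (mh$length == 0)
    expect_equal(leftmost_normalize(ev, genome)$ref_interval$start, 8)
  inv <- sv_event("i", "INV", gint("c1", 5, 15))
  expect_identical(leftmost_normalize(inv, genome)$ref_interval$start, 5)
})

test_that("insertion left-alignment rotates the inserted sequence", {
  ## reference ...AAC | AAC inserted: can shift left across the repeat
  genome <- c(c1 = "GGTTCAACGGTGCA")
  ev <- sv_event("i", "INS_UNIQUE", gint("c1", 7, 8),
                 inserted_sequence = "CAA",
                 params = list(insertion_point = 7))
  norm <- leftmost_normalize(ev, genome)
  expect_lt(norm$params$insertion_point, 7)
  ## derived sequences identical
  derived <- function(p, ins) paste0(substr(genome, 1, p), ins,
                                     substr(genome, p + 1, nchar(genome)))
  expect_identical(derived(norm$params$insertion_point,
                           norm$inserted_sequence),
                   derived(7, "CAA"))
})

test_that("complex events must have adjacent components", {
  expect_error(
    sv_event("x", "DEL_INV", gint("c", 100, 300), components = list(
      list(type = "del", interval = gint("c", 100, 150)),
      list(type = "inv", interval = gint("c", 160, 300)))),
    "adjacent")
})
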