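chrom_len <- c(chr19 = 1e6)
features <- data.frame(chrom = "chr19",
                       start = seq(0, 990000, by = 10000),
                       end = seq(0, 990000, by = 10000) + 600)

test_that("maximal enrichment gives the minimal corrected p", {
  svs <- data.frame(chrom = "chr19", start = features$start[1:20] + 50,
                    end = features$start[1:20] + 250)
  res <- permutation_overlap_test(svs, features, chrom_len,
                                  n_perm = 199, seed = 4)
  expect_equal(res$observed_overlaps, 20L)
  expect_equal(res$empirical_p, 1 / 200)
  expect_gt(res$fold_change, 1)
  expect_equal(res$direction, "enrichment")
})

test_that("the permutation test is deterministic per seed", {
  set.seed(1)
  svs <- data.frame(chrom = "chr19",
                    start = s <- round(runif(40, 0, 9.9e5)),
                    end = s + 500)
  r1 <- permutation_overlap_test(svs, features, chrom_len, n_perm = 99,
                                 seed = 12)
  r2 <- permutation_overlap_test(svs, features, chrom_len, n_perm = 99,
                                 seed = 12)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_identical(r1$empirical_p, r2$empirical_p)
  expect_true(r1$empirical_p > 0 && r1$empirical_p <= 1)
})

test_that("gap regions are excluded from permutation placement", {
  gaps <- data.frame(chrom = "chr19", start = 0, end = 5e5)
  set.seed(2)
  svs <- data.frame(chrom = "chr19",
                    start = s <- round(runif(30, 5e5, 9.9e5)), end = s + 400)
  res <- permutation_overlap_test(svs, features, chrom_len, gaps = gaps,
                                  n_perm = 99, seed = 3)
  ## null placements live entirely in the allowed half, so the null mean
  ## reflects only the features there
  expect_gt(res$null_mean, 0)
  ## an SV longer than every gap-free segment cannot be placed
  giant <- data.frame(chrom = "chr19", start = 0, end = 9e5)
  expect_error(
    permutation_overlap_test(giant, features, chrom_len,
                             gaps = data.frame(chrom = "chr19",
                                               start = 45e4, end = 55e4),
                             n_perm = 99, seed = 1),
    "placement-failure")
})

test_that("fold change near 1 under null placement", {
  set.seed(3)
  svl <- round(runif(120, 200, 2000))
  svs <- simulate_sv_placements(svl, features, chrom_len, fold = 1)
  res <- permutation_overlap_test(svs, features, chrom_len, n_perm = 199,
                                  seed = 5)
  expect_lt(abs(res$fold_change - 1), 0.35)
})

test_that("report_cohort aggregates calls and handles empty input", {
  mk <- function(p) structure(list(pattern = p, code = pattern_code(p),
                                   complexity = pattern_complexity(p)),
                              class = "pattern_call")
  calls <- lapply(c(rep("H1", 6), rep("H5", 2), "Q6", "Q7", "no_call"),
                  function(p) if (p == "no_call")
                    structure(list(pattern = "no_call", code = NA),
                              class = "pattern_call") else mk(p))
  rep <- report_cohort(calls)
  expect_equal(sum(rep$adjudication), 1)
  expect_equal(unname(rep$pattern_counts["H1"]), 6L)
  expect_equal(rep$n_no_call, 1L)
  expect_equal(unname(rep$adjudication["simple"]), 0.6)
  empty <- report_cohort(list())
  expect_equal(sum(empty$pattern_counts), 0L)
  ## confusion matrix with truth
  truth <- c(rep("DEL_UNIQUE", 6), rep("DEL_INV", 2),
             "RETROGENE_FALSE_DEL", "VNTR", "INV")
  rep2 <- report_cohort(calls, truth = truth)
  cm <- rep2$confusion
  expect_equal(sum(cm), 11L)
  expect_equal(unname(cm["DEL_UNIQUE", "DEL_UNIQUE"]), 6L)
  expect_equal(unname(cm["INV", "no_call"]), 1L)
})
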