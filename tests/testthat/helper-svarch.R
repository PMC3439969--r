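## Shared fixtures: a small config with a fixed toy repeat library so
## helper objects are cheap and reproducible across test files.

test_config <- function(seed = 1L, ...) {
  set.seed(9000)
  lib <- default_repeat_library()
  sim_config(seed = seed, repeat_library = lib, ...)
}

insert_stats <- function(config) {
  list(mean = config$insert_mean, sd = config$insert_sd)
}

## derived sample sequence after deleting [s, e) (0-based half-open)
apply_deletion_str <- function(x, s, e) {
  paste0(substr(x, 1, s), substr(x, e + 1, nchar(x)))
}

## brute-force placement oracle: all starts s2 such that deleting
## [s2, s2 + w) yields the same derived sequence as deleting [s, e)
equivalent_placements <- function(x, s, e) {
  w <- e - s
  target <- apply_deletion_str(x, s, e)
  hits <- integer()
  for (s2 in 0:(nchar(x) - w)) {
    if (apply_deletion_str(x, s2, s2 + w) == target) hits <- c(hits, s2)
  }
  hits
}

## worked-example junction: motif duplicated at both breakpoints of a
## deletion, with forced mismatches so homology is exactly the motif
make_mh_locus <- function(motif, core_len, flank = 80L) {
  k <- nchar(motif)
  repeat {
    P <- random_dna(flank); S <- random_dna(flank)
    C <- random_dna(core_len - k)
    if (substr(C, 1, 1) != substr(S, 1, 1) &&
        substr(C, nchar(C), nchar(C)) != substr(P, flank, flank)) break
  }
  ref <- paste0(P, motif, C, motif, S)
  list(ref = ref, s = flank, e = flank + core_len, k = k,
       carrier = paste0(P, motif, S))
}
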