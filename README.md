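# svarch

Fine-scale architecture of structural variants (SVs) from paired-end
mapping signatures and assembled breakpoint sequences.

## The problem

Short-read SV callers recognize four basic event types — deletions,
insertions, inversions and copy-number gains — from the geometry of
mapped read pairs: a pair mapping in forward–reverse (FR) orientation at
a distance far larger than the library insert indicates a deletion;
FF/RR pairs an inversion; RF pairs a tandem duplication; a read whose
mate fails to map (an "orphan") novel inserted sequence. But real
rearrangements in mammalian genomes are frequently *complex*: two or
more SV types directly abutting with no intervening DNA of normal
structure (an inversion flanked by deletions, a deletion with a novel
insertion at its junction), plus retrogene artifacts that mimic
deletions and inversions without any rearrangement at all. At finer
scale still, roughly a quarter of "simple" SVs carry bp-scale
micro-insertions and micro-deletions at their junctions, along with
micro-homology, target-site duplications (TSDs) and poly(A)/poly(T)
tails that point at the mutational mechanism (retrotransposition vs
microhomology-mediated replication repair).

`svarch` is for method developers and analysts who need this fine
structure as *testable code*: a simulator that plants a 21-pattern
catalog of paired-end mapping (PEM) signatures with realistic breakpoint
micro-architecture and ground truth, a rule-based classifier that
recovers the pattern from read-pair evidence, a nucleotide-resolution
breakpoint analyzer for assembled multi-strain locus sequences, and a
permutation test for SV/feature overlap enrichment. The default strain
panel is the eight classical inbred mouse strains (A/J, AKR/J, BALB/cJ,
C3H/HeJ, C57BL/6J, CBA/J, DBA/2J, LP/J; C57BL/6J is the reference), and
variants carry strain distribution patterns (SDPs) such as `11110101`.

## Core statistics and conventions

* **PEM patterns.** 21 patterns, H1–H11 (high confidence) and Q1–Q10
  (questionable), each adjudicated simple / complex / false / VNTR;
  `pem_pattern_table()` is the catalog. Classification is an ordered
  rule cascade over depth states (zero/loss/normal/gain relative to the
  locus-flank median), discordant-pair clusters by orientation class
  (`long_FR`, `short_FR`, `FF`, `RR`, `RF`) and orphan clusters.
* **Micro-homology (MH).** For a deletion `[s, e)` the MH length is the
  largest `k` with `ref[s + i] == ref[e + i]` (searched in both
  directions), i.e. the number of alternative equivalent placements of
  the junction; `k = 0` is a blunt end. Ambiguous junctions are
  reported at their left-most placement (`leftmost_normalize()`).
* **Coordinates.** Internally 0-based half-open; printed/VCF coordinates
  are 1-based inclusive and converted only at I/O
  (`from_paper_coords()`, `to_paper_coords()`). The span printed as
  `chr10:20,467,348-20,467,894` has length 547.
* **Enrichment.** `permutation_overlap_test()` re-places each SV
  uniformly on its chromosome (length-preserving, gap-aware,
  non-overlapping) and reports fold change and a two-sided empirical p
  with the `(1 + k)/(n + 1)` correction.

## Worked example

Simulate an inversion flanked by two deletions — a complex architecture
whose read-pair signature changes with the inversion's size relative to
the 3 kb insert — and classify it from its own reads:

```r
library(svarch)
cfg <- sim_config(seed = 1)
set.seed(1)
sl <- simulate_locus("DEL_INV", cfg)
classify_locus(sl$pairs, sl$locus, sl$annotation,
               list(mean = cfg$insert_mean, sd = cfg$insert_sd))
#> <pattern_call> H5 -> DEL_INV (complex, high)  sim:[26614,41966)
#>   inversion evidence with flanking zero-depth deletions
```

The call is pattern H5 (inversion co-occurring with deletions), complex,
high confidence; the interval is the union of the junction evidence
around the true event at `sim:[30000,38448)`.

Breakpoint-level analysis of a simulated Sanger-style cohort:

```r
co <- simulate_cohort(sim_config(seed = 1,
        cohort_design = c(ancestral_deletion = 30,
                          ancestral_insertion = 20,
                          inversion = 3, gain = 2)))
reps <- analyze_cohort(co)
reps[[1]]
#> <breakpoint_report> DEL_001: deletion [500,1049) len 549
#>   micro-ins 7 bp, micro-del 0 bp, MH 22 bp, TSD 0 bp (not_applicable)
#>   ancestry ancestral_deletion, SDP 01100110
round(summarize_breakpoint_features(reps)$percent, 1)[1:2, 1:2]
#>                        ancestral_insertion ancestral_deletion
#> None                                    95               76.7
#> Micro-deletion 1-34 bp                   5                0.0
```

Locus `DEL_001` is a 549 bp deletion relative to the reference, placed
left-most under its 22 bp of junction micro-homology, carrying a 7 bp
micro-insertion; the outgroup allele retains the segment, so the event
is an ancestral deletion present in strains 2, 3, 6 and 7 of the panel.

## Command line

A `svarch` front end (see `inst/exec/svarch`, or call `svarch_cli()`):

```sh
svarch simulate    --out demo --seed 3            # cohort + truth files
svarch breakpoints --loci demo/loci --out bp      # junction reports
svarch classify    --sam A_J.sam --locus chr19:10000-40000 --out calls
svarch enrich      --svs svs.bed --features repeats.bed \
                   --chrom-lengths lens.tsv --n-perm 999 --seed 7 --out enr
```

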