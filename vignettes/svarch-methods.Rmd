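---
title: "Models and methods behind svarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind svarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(svarch)
```

`svarch` treats the fine-scale architecture of structural variants as a
round-trip problem: a generative model plants rearrangements with known
breakpoint micro-structure, and two analyzers — a read-pair pattern
classifier and a sequence-level breakpoint analyzer — must recover what
was planted. This vignette records the models, the tunable parameters
and their defaults, the numerical choices, and what a green test does
and does not establish.

## The pattern catalog and its evidence model

A locus is summarized by a *PEM signature*: a windowed read-depth
profile segmented into copy-number states, clusters of discordant read
pairs keyed by orientation class, and clusters of orphaned mates
(mapped reads whose partner lies in novel sequence). Twenty-one
patterns are distinguished (`pem_pattern_table()`): eleven
high-confidence H patterns and ten questionable Q patterns, each
adjudicated simple, complex (two or more SV types directly abutting
with no intervening DNA of normal structure), false (retrogene
artifacts) or VNTR. The 21 patterns map onto 19 architecture codes: the
microsatellite and VNTR patterns (Q1/Q7) share one code, as do the two
deletion-plus-insertion patterns (Q2/Q3).

Classification is an ordered cascade from most to least specific
evidence: retrogene exon-skipping geometry, then annotated tandem
repeat arrays, then gain-context rules, then the inversion family, the
deletion family, and finally pure insertions; anything else is an
explicit no-call. Two discriminations deserve comment:

* **Linked gains (Q5/Q9) versus adjacent duplications (H8/H9).** Both
  produce gains plus discordant clusters. Footprint separation turned
  out to be unreliable (junction-spanning fragments bridge the
  source-to-copy gap), so the defining property used is the one in the
  catalog itself: linked gains are *small*. A total gain-state width of
  at most `small_gain_max` (2 kb) with strictly normal depth elsewhere
  is linked; larger gains follow the duplication/dispersed rules.
* **Direct versus inverted retrogenes (Q6/Q10).** Exon-to-exon pairs
  inside the processed copy read as long-FR "intron deletions"
  whichever way the copy points. What flips with an inverted copy are
  the pairs bridging the insertion site, which become FF/RR links
  anchored in the gene's exons; their presence is the Q10 signal.

The published catalog was assembled by visual inspection and states no
thresholds, so every cutoff is exposed in `classifier_params()`:
`min_support = 3` pairs per cluster, insert discordance at `k_sd = 4`
SDs, single-linkage merge distance equal to the insert mean, depth
states at 0.1/0.6/1.4 of the locus-flank median with a two-window
minimum run (three for gains, which sit closer to the noise floor), a
500 bp normal-copy gap for Del+Nml+Del (H3, measured gaps get a
two-window quantization allowance), a 100 kb large-deletion threshold
(Q4), 50% repeat overlap for the repeat flavours (H2/Q3), and a 6 bp
microsatellite unit ceiling (Q1 vs Q7).

An inversion flanked by deletions (H5) changes signature with size: if
the inverted core is shorter than the insert, fragments span the whole
event and the pair geometry reads as one deletion. The classifier does
not depend on the FF/RR clusters alone for H5 — the zero-depth flanks
adjacent to any inversion evidence force the complex call, which is
what makes the rule robust on both sides of the insert size.

## The generative model

`simulate_locus()` builds, per architecture code, a dedicated random
chromosome (60–360 kb) containing exactly the context the code needs: a
LINE-like copy to delete, a tandem repeat array with per-strain unit
counts, a multi-exon toy gene whose processed copy is re-inserted
distally, and so on. Haplotypes are expressed as piecewise segment maps
to the reference (forward, reverse-complement, or novel), and read
pairs are *placed through the map rather than mapped*: fragment lengths
are N(`insert_mean`, `insert_sd`), each read lands by the majority-
overlap side of any junction it straddles, reads majority-inside novel
sequence are emitted unmapped, and strands flip inside inverted
segments. No error model, base qualities, or mapping ambiguity are
simulated: the evidence the classifier consumes is mapped-pair
geometry, and keeping placements exact keeps the tests exact. This is
also the main limit of what a green round-trip establishes — it
validates the interpretation rules, not robustness to mapping artifacts
in repetitive sequence.

The library insert size of the source data is not reported; the
defaults `insert_mean = 3000`, `insert_sd = 300`, `read_length = 100`,
`depth = 30` are package assumptions, chosen so that the H5
size-dependence is exercisable on both sides of the insert and stated
once here. Strains are inbred, i.e. haploid in effect: deletions are
homozygous and produce zero-depth windows. The toy repeat library is
random sequence at canonical element sizes (6 kb LINE-like, 300 bp
SINE-like with A-tail, 1.2 kb ERV-like); real consensus sequences are
deliberately not shipped.

## Breakpoint micro-architecture

The sequence-level cohort (`simulate_cohort()`) follows the survey
design of 261 simple SV loci across 8 strains — 105 ancestral
insertions, 142 ancestral deletions, 6 inversions, 8 gains; counts are
fixed, not sampled — contributing 4,176 breakpoints (261 x 8 x 2) to
the manifest. Junction micro-features are drawn per ancestry class from
`breakpoint_feature_frequencies()`: micro-insertions at deletion
junctions (26.7% overall: 19.7% of 1–10 bp, 5.6% of 11–50 bp, 1.4%
above 51 bp, capped at the largest observed 107 bp), micro-deletions at
insertion junctions (15.2%, up to 289 bp), the inversion column (two
thirds micro-deletion, one third both), and gains (12.5%
micro-insertion). Size bins are sampled uniformly; the open bins close
at the observed maxima. The inversion column contains no "none" row, so
every simulated inversion locus carries a micro-event, and its "both"
bins are applied to both event lengths since the table does not say
which event they describe.

On top of the per-class columns: deletion junctions carry
micro-homology with probability 0.5 (3–25 bp, matching the observation
that about half of complex non-retrotransposon SVs show 3–25 bp of
junction homology), 4.5% of ancestral deletions carry two SNPs inside
their micro-homology shared by *all* carrier strains, retrotransposon
insertions get a 5–20 bp TSD and a poly(A) tail or poly(T) head except
for a 15% fraction modeling integration into pre-existing DNA lesions
(no TSD, truncated or absent tail), 16% of insertions carry a SNP
inside the TSD, and micro-insertion origins are drawn uniformly over
the three observed routes (intra-chromosomal copy, inter-chromosomal
copy, retrotransposon fragment) when the sequence is long enough to
classify (>= 10 bp).

Alleles are assembled from explicit pieces with a *forced mismatch at
every junction boundary*. This is the load-bearing numerical choice of
the generator: without it, accidental sequence identity extends
homology past the planted length with probability ~1/4 per boundary,
and exact round-trip assertions would be impossible. With it, every
planted feature — micro-insertion sequence, micro-deletion length, MH
length and sequence, TSD, poly-tail class, SNP positions — is recovered
verbatim, and the test suite asserts equality, not approximation.

## Breakpoint analysis

`locate_breakpoints()` walks in from both ends of a carrier/non-carrier
pair: the first breakpoint is where the alleles stop matching, the
second where they resume; the unaligned middles feed
`call_micro_events()`. An isolated mismatch is recorded as a SNP and
skipped when followed by 8 clean matching bases, so strain SNPs do not
truncate flank alignment; a shorter look-ahead (5 bases) was measurably
coincidence-prone at cohort scale (~0.1% of junctions misread per
side). One consequence: the generator plants co-segregating
micro-homology SNPs only in homologies of 18 bp or more, so each SNP
retains 8 clean bases of context — shorter SNP-bearing homologies,
which do occur in real data, are exercised directly through the
region-based co-segregation test instead. A banded affine-gap aligner
was considered for flank anchoring and dropped: on error-free assembled
sequences the exact walk returns the same decomposition and is both
faster and easier to reason about; anchoring still requires >= 90%
identity over 50 bp flanks, and junction middles are interpreted by
reverse-complement overlap (inversions, minimum 30 bp core),
adjacent-copy stripping (duplications, minimum 50 bp — deliberately
above the 30 bp TSD search ceiling so TSDs are never mistaken for
tandem copies), or length difference (deletion/insertion).

When prefix and suffix matches overlap (micro-homology), the suffix is
clipped, which yields the right-most junction; the reported span is
then canonicalized to the smallest coordinates by
`leftmost_normalize()`, and a blunt junction keeps its single
placement. `find_microhomology()` counts matching bases in both
directions from the given placement, so its result equals the number of
alternative placements regardless of which placement is supplied — the
exhaustive-enumeration oracle in the tests checks exactly this.
Ancestry is polarized by which allele arrangement the outgroup matches
(outgroup lacks the sequence: the bearing allele is an ancestral
insertion; outgroup carries it: the lacking allele is an ancestral
deletion); inversions and gains are not polarized. Micro-insertion
origin search uses >= 90% identity on both strands with ties broken
retrotransposon > intra > inter, the repeat identity being the more
specific claim.

## Permutation enrichment test

The null model re-places every SV uniformly at random on its own
chromosome, preserving length, avoiding gap regions and overlap among
placed SVs; per-chromosome counts and the length spectrum are preserved,
inter-SV spacing is not (the simplest length-preserving scheme — the
original analysis does not specify its shuffling unit, so SV-shuffling
is implemented and flagged here). Overlap is counted per SV (>= 1 bp),
not per base. The empirical p uses the add-one correction
`(1 + #extreme)/(n_perm + 1)` on absolute deviations from the null
mean, with direction reported separately. Overlap counts are integers;
the tie mass alone made the null p distribution detectably non-uniform,
so ties in the count deviation are broken by a secondary,
near-continuous statistic (total overlapped base pairs). This keeps the
p-value's null distribution uniform to Kolmogorov–Smirnov tolerance
while preserving the correction and the minimal attainable p of
`1/(n_perm + 1)`.

`simulate_sv_placements()` is the matching synthetic placement model
for calibration and recovery experiments: a rejection sampler whose
acceptance weights raise each SV's overlap probability to `fold` times
its own analytic uniform base rate, so a planted fold change is
recovered without length-composition bias.

## Degenerate inputs and failure modes

Zero-length intervals are rejected at construction; insertions use a
one-base anchor interval plus an explicit insertion point. Zero flank
coverage makes depth normalization impossible and is an error; a locus
with flat depth and no clusters is a no-call, never a fabricated
pattern. Flanks that fail the 90% anchor are an `unanchored-locus`
error. An SV longer than every gap-free segment is a
`placement-failure` naming the SV. Clusters below `min_support` are
silently discarded. Triple-compound rearrangements (three or more SV
types at one locus) are outside the rule set by design and fall to
no-call with their evidence preserved.

## Known limitations

No sequencing error, base-quality or mapping-ambiguity model; no
split-read or assembly evidence; repeat/unique discrimination is purely
annotation-driven; carrier strains share one haplotype per locus
(real strains differ by private variation the Sanger survey had to read
through); the VNTR model maps the shortened array as a prefix of the
reference array, which reproduces the deletion-like evidence but not
the true dispersed mapping of repeat reads; and multi-allelic SDP
values (2–4) are stored but interpreted only as "present, distinct
allele", since no allele semantics are defined for them.
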