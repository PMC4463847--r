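---
title: "Methods: identifying and characterising natural antisense transcripts"
author: "natscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and characterising natural antisense transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natscape)
```

# The problem

Natural antisense transcripts (NATs) are endogenous RNAs that can base-pair
with another transcript and form double-stranded RNA.  A *cis*-NAT pair is
transcribed from overlapping positions of the same locus on opposite
strands, so its overlap is perfectly complementary; a *trans*-NAT pair
comes from separate loci and is only partially complementary.  NAT pairs
matter because their double-stranded region can be diced into small
interfering RNAs (NAT-siRNAs) and because the two genes of a pair often
share a chromatin and DNA-methylation state.

`natscape` implements a complete desk-scale pipeline over standard genomics
formats: cis-NAT orientation classification, trans-NAT discovery by
reverse-complement alignment with a duplex "bubble" rule, NAT-siRNA calling
from small-RNA alignments, an overlap-enrichment statistic, histone-mark
pair-pattern classification against a randomized null, a binned
DNA-methylation distance with a resampled null, and a coexpression network.
A synthetic-data generator plants known structure in every one of these
layers, so each stage can be validated against ground truth without any
external download.

# Coordinate conventions

All internal coordinates are 0-based, half-open (`[start, end)`).  GFF3 and
other 1-based inclusive formats are converted at the I/O boundary only, so
interval arithmetic is everywhere `end - start`.  For a `-` strand feature
the 5' end is the `end` side; orientation-sensitive logic goes through
`five_prime()`/`three_prime()` rather than raw coordinates.

# cis-NAT classification

Two transcripts on the same chromosome and opposite strands form a cis
pair when their full genomic spans overlap by at least `min_overlap` nt
(default 1; no minimum is standard in the field) or lie within
`nearby_max_gap` nt of each other.  Orientation is decided by which ends
meet:

* **containing** — one span nested in the other (equal spans count as
  containing; the categories must be mutually exclusive and nesting is
  checked first);
* **convergent** — tail-to-tail overlap of the two 3' ends;
* **divergent** — head-to-head overlap of the two 5' ends;
* **nearby head-to-head / tail-to-tail** — no overlap, the facing ends
  decide the label.

Design notes.  Overlap is computed on full transcript spans ("overlap in
the genome"), with exonic-mode computation deliberately out of scope for
the default path.  The nearby distance cutoff is genuinely unstated in the
genome-wide NAT literature; we default to 100 nt, expose it in the
configuration, and record it in every output header.  Pairs are found per
transcript and deduplicated to gene level keeping the longest overlap,
since genome-scale NAT tables count gene pairs.  Nearby pairs are tagged
but excluded from all downstream statistics by default, matching the usual
analytical focus on the overlapping subtypes.

# trans-NAT discovery

Each transcript is aligned locally against the reverse complement of every
other (match +1, mismatch −2, gap open 5, gap extend 2, DNA space).  An
indexed prefilter only aligns pairs sharing at least `min_shared = 2` exact
13-mers between one sequence and the other's reverse complement; a genuine
100-nt duplex region at 80% identity is expected to contain several exact
13-mers, while unrelated transcripts rarely share more than one.  The
alignment itself is windowed around the shared seeds (seed-and-extend) with
a pad of `min_region` nt.  Candidates need an aligned region of at least
`min_region = 100` nt at identity `min_identity = 0.8`; these two
thresholds are engineering defaults, not published constants, and are
logged in the output.

Duplex verification is deterministic base-pairing rather than
thermodynamics: positions of the alignment are paired iff they are
Watson–Crick complementary (optionally G:U wobble), and every maximal run
of unpaired columns is a *bubble*.  A pair is accepted iff its longest
bubble is no longer than 10% of the pairing region, boundary inclusive.
The region is measured in alignment columns so that the verdict is
symmetric in the two transcripts even when the bubble is an insertion on
one side.  Free-energy computation is intentionally absent: the acceptance
criterion is geometric and nothing downstream consumes ΔG.

# Small-RNA library and NAT-siRNA calling

The library filter retains reads that (i) do not overlap an excluded
structural/regulatory ncRNA locus (rRNA, snRNA, snoRNA, miRNA — tRNA loci
are deliberately preserved), (ii) map to exactly one genomic locus, and
(iii) are 18–28 nt long.  A distinct sequence becomes a NAT-siRNA iff its
locus lies fully inside the overlap/pairing region of at least one NAT
pair and the sequence is observed in at least three data sets.
Reproducibility is counted by exact sequence identity across data sets
(locus mode available); any three data sets qualify regardless of tissue.
The producing transcript of a source pair is the member whose strand
matches the read; a locus belonging to several pairs' regions is called
once and flagged `nonunique`, reconciling the single-genomic-locus mapping
rule with multi-pair membership.

# Overlap enrichment statistic

For one pair and one data set, `N_o` distinct siRNA loci fall fully inside
the overlap region of length `L_o`, and `N_g` inside the union of the two
gene spans minus the overlap (length `L_g`; shared nucleotides counted
once).  The densities are `N_o/L_o` and `N_g/L_g`; their means over pairs
are `A_o` and `A_g`, and the enrichment score is `R = A_o/A_g`.
Significance is a paired two-sample t-test across the pairs of one data
set, one-tailed in the enrichment direction, df = n − 1.  Containment
(not any-overlap) defines membership, because with 18–28-nt reads
containment is the only unambiguous reading of "mapping to the overlapping
region"; an any-overlap mode is a flag.  Degenerate data (all per-pair
differences zero) reports t = 0, p = 0.5 rather than NA so that empty
data sets stay visible in the Table-layout output.

`enrichment_calibration()` simulates data sets under the same Poisson
locus-placement scheme as the generator and is used to verify that the
test's type-I error at α = 0.05 stays within binomial tolerance of
nominal and that power under a 5× planted rate ratio exceeds 0.95 at 50
pairs.

# Chromatin pair patterns

Enriched tiles per mark are joined into domains when the edge-to-edge gap
is at most 200 nt (inclusive), and merged intervals shorter than 400 nt
are discarded.  A mark targets a gene iff a domain overlaps the gene span
by ≥ 1 nt (the overlap rule is unstated in the source methods; promoter
inclusion is behind a flag).  Marks split into euchromatic G1 (H3K4me2,
H3K4me3, H3K36me3, H2Bub) and heterochromatic G2 (H3K27me1, H3K27me3);
genes are G1, G2, G1+G2 or NON, and a pair's unordered state combination
is one of ten classes (G1_G1 … NON_NON).  The randomized null draws, in
each of 10,000 repeats, as many random non-NAT gene pairs as observed
(without replacement within a repeat — replacement is unstated in the
field's descriptions; we chose the option that cannot pair a gene with
itself), and reports the mean class percentages with a 2.5/97.5 percentile
envelope so that direction can be asserted, not just compared to a mean.

# DNA-methylation distance

Absolute methylation level is pooled per bin: the sum of methylated reads
over the sum of coverage across the cytosines of one context (CG, CHG,
CHH) in the bin, both strands combined, 20 bins per region, oriented
5'→3'.  Two regions are supported: the gene body and a 1-kb promoter
upstream of the TSS.  The methylation distance of a pair is
`D_mC = 1 − r`, Pearson's r over mutually covered bins, undefined (never
zero) with fewer than 3 shared bins or zero variance.  The correlation
support is genuinely ambiguous in the source literature (bins vs samples);
we correlate across positional bins by default and provide a sample-wise
mode.  Observed pair distances are compared with distances of randomized
non-NAT pairs (10,000 by default) by a one-tailed Wilcoxon rank-sum test.

# Coexpression network

Genes present in fewer than three data sets are removed; the Pearson
correlation of a pair's expression is computed over samples where both
genes are present (absent means missing, not zero).  Edges require
`|PCC| ≥ 0.8` — figure legends in the field use ≥ while running text says
>, and we adopt the inclusive reading with a `strict_gt` flag.  Edges are
annotated with NAT-siRNA production and with modification similarity, the
correlation of the two genes' concatenated six-mark binary domain-overlap
profiles over body bins (the support of "modification pattern similarity"
is unstated; this choice is recorded here).  dsRNA coverage support is an
edge attribute, not a filter.

# The synthetic generator

`synth_config()`/`generate_bundle()` produce a complete input set:

* a random-sequence genome with planted cis pairs of every subtype
  (slot-based placement guarantees no unintended overlaps, so recovery
  tests are exact) and trans pairs built by inserting the reverse
  complement of a segment of one transcript into another chromosome, with
  an optional central deletion in the copy that creates a bubble of
  configurable relative length;
* small-RNA loci placed by a Poisson process at 0.03 loci/nt inside
  overlap regions and 0.005 loci/nt in the remaining gene body, lengths
  drawn with mass concentrated at 21 and 24 nt, each locus observed in
  each of 4 data sets with probability 0.9 — the identical presence
  mechanism in both region types means equal rates give an exact null for
  the enrichment score;
* chromatin tiles realising a per-gene latent state drawn from
  (G1 45%, G2 30%, G1+G2 15%, NON 10%), with the second gene of a pair
  copying the first's state with probability 0.9;
* methylation profiles per context drawn from Beta gene-level means (CG
  mean 0.7, CHG 0.3, CHH 0.1) with an across-bin noise profile shared
  within concordant pairs (bin sd 0.15, per-gene deviation sd 0.03),
  cytosines every 30 nt at coverage 20;
* log-normal expression over 15 samples with correlation 0.95 planted in
  60% of pairs and 10% of cells missing.

These defaults are the study conditions of the package's tests; the
generator emulates the *statistical* structure of real data (rates,
concordances, correlations), not its sequence composition, read errors or
assembly artefacts, so passing recovery tests demonstrates correctness of
the algorithms, not performance on real libraries.  One global seed feeds
fixed per-layer offsets, so regenerating a single layer never perturbs
gene placement.

# Problem sizes and numeric choices

The bundled validation uses a two-chromosome, 80-gene bundle for module
tests; a five-chromosome, ~530-gene bundle for exact planted-recovery
checks; 1,000 simulated data sets of 50 pairs for t-test calibration;
10,000 repeats for the pattern null (matching the published procedure);
and 300–400 randomized pairs per seed across 25–50 seeds for the D_mC
null, which keeps the whole suite within a few minutes while leaving
Monte-Carlo error well below the asserted tolerances.  Ties and degenerate
inputs are always flagged (NA plus a reason) rather than coerced to 0, and
every randomized procedure takes an explicit seed and is reproducible
byte-for-byte.

# Known limitations

* Exon-aware overlap (splicing) is not the default anywhere; all region
  logic uses genomic spans.
* The trans-NAT search is heuristic (seeded, windowed alignment); a
  sufficiently degenerate duplex below two shared 13-mers would be missed.
* No thermodynamic duplex stability, no coding-potential model (coding
  probabilities are consumed as input), no GO enrichment, no plotting of
  the published figures.
* The methylation generator does not constrain site contexts to be
  consistent with the random genome sequence; readers and statistics never
  inspect sequence context beyond the context label.
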