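# natscape

Genome-wide identification and characterisation of **natural antisense
transcripts (NATs)** in R.

NATs are endogenous transcripts that can base-pair with another transcript
and form double-stranded RNA. `natscape` is for genomicists who have a
genome annotation, small-RNA alignments, chromatin enriched-tile calls,
per-cytosine methylation calls and an expression matrix, and want the full
NAT analysis over them:

* **cis-NAT pairs** — opposite-strand overlapping (or nearby) gene pairs,
  classified as *convergent* (tail-to-tail), *divergent* (head-to-head),
  *containing* (nested), or *nearby head-to-head / tail-to-tail*;
* **trans-NAT pairs** — pairs from separate loci found by local alignment
  of each transcript against the reverse complement of every other,
  accepted when the duplex's longest unpaired run ("bubble") is at most
  10% of the pairing region;
* **NAT-siRNAs** — distinct 18–28-nt, uniquely mapping small-RNA sequences
  whose locus lies inside a pair's overlap/pairing region and which recur
  in ≥ 3 data sets (rRNA/snRNA/snoRNA/miRNA reads removed, tRNA reads
  preserved);
* the **overlap enrichment score** `R = A_o / A_g`, the ratio of the mean
  siRNA locus density in overlap regions (per pair: `N_o / L_o`) to the
  mean density in the genes' non-overlapping portions (`N_g / L_g`), with
  a one-tailed paired two-sample t-test across pairs;
* **histone pair patterns** — genes are G1 (euchromatic marks: H3K4me2,
  H3K4me3, H3K36me3, H2Bub), G2 (heterochromatic: H3K27me1, H3K27me3),
  G1+G2 or NON after joining enriched tiles into domains (gap ≤ 200 nt,
  domain ≥ 400 nt); each pair falls in one of ten unordered classes
  (G1_G1 … NON_NON), compared against 10,000 randomized non-NAT pairs;
* the **DNA-methylation distance** `D_mC = 1 − r` (Pearson r over binned
  CG/CHG/CHH levels in promoter or gene body), tested against randomized
  pairs with a one-tailed Wilcoxon rank-sum test;
* the **coexpression network** — edges for pairs with `|PCC| ≥ 0.8` over
  shared expression samples, annotated with NAT-siRNA production and
  histone-profile similarity.

A synthetic-data generator (`synth_config()` / `generate_bundle()`) writes
every input format with planted NAT geometry, siRNA enrichment, epigenetic
concordance and coexpression, so the entire pipeline is testable offline;
`truth_table()` exposes the planted ground truth.

## Worked example

```r
library(natscape)

cfg    <- synth_config(seed = 1)                  # 80-gene toy study
bundle <- generate_bundle(cfg, dir = "nat_demo")  # writes all input files

catalog <- read_gff3("nat_demo/annotation.gff3")
cis     <- find_cis_pairs(catalog$transcripts)
table(cis$subtype)
#>          containing          convergent           divergent
#>                   5                   5                   5
#> nearby_head_to_head nearby_tail_to_tail
#>                   3                   3

trans <- find_trans_pairs(read_fasta("nat_demo/transcripts.fa"),
                          catalog$transcripts)
nrow(trans)
#> [1] 4

lib    <- build_library(read_smrna_table("nat_demo/smrna.tsv"),
                        read_tiles("nat_demo/exclusion.bed"))
pairs  <- cis[!is.na(cis$overlap_start), ]   # overlapping subtypes only
called <- call_nat_sirnas(lib$library, pairs, catalog$transcripts)
summarize_sirnas(called)$length_histogram
#>  18  19  20  21  22  23  24  25  26  27  28
#>   7  10  12 108  21   8  76  10  17   7   9

enrichment_test(pairs, lib$library, catalog$transcripts, dataset = "D1")
#>   dataset_id stratum n_pairs        A_o         A_g        R  t_stat      p_value
#> 1         D1     all      15 0.02817572 0.004803744 5.865367 7.92673 7.620135e-07
```

Every planted subtype count is recovered exactly; the called NAT-siRNAs
show the planted 21/24-nt length bias; and the enrichment score `R ≈ 5.9`
with `p = 7.6e-07` recovers the planted 6× overlap-vs-background locus
rate (0.03 vs 0.005 loci/nt). `run_pipeline(pipeline_config(...), out_dir)`
chains all stages (catalog → cis/trans → siRNA → enrichment → chromatin →
methylation → network) and writes one TSV per stage, reproducibly for a
given seed.

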