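# switchtome

Genome-scale analysis of strand-specific time-course RNA-seq across the
metabolic switch of *Saccharopolyspora erythraea* (and similar
actinomycetes with circular chromosomes).

When an actinomycete batch culture exhausts its preferred nutrients, growth
arrests and the transcriptome is rearranged on a genome-wide scale: large
core and non-core chromosomal macro-regions alternate in expression,
transposon clusters at the region borders are transiently induced,
ribonucleases spike, total mRNA passes through a concentration
"bottleneck", and degradation is targeted to specific mRNA classes.
`switchtome` implements the quantitative toolkit for detecting and
measuring these phenomena from per-base coverage tracks and per-gene count
tables, together with a fully parameterised synthetic-data generator that
carries ground truth for recovery and calibration testing.

## What it computes

For genes `g`, timepoints `t`, and libraries with totals `N`:

- **Pervasive transcription / saturation** — fraction of genomic positions
  with pooled coverage ≥ *min_cov* from either strand or ignoring strand,
  and the fraction of expressed nucleotides represented singly.
- **Strand preference** — per bin, `P = (L − G)/(L + G)` where `L` and `G`
  are leading- and lagging-strand coverage, with the replichore of each
  position determined by the replication origin and terminus.
- **Macro-region enrichment** — per region `r` and timepoint,
  `E(r,t) = log2(mean expression in r / genome mean)`, the core-referenced
  contrast `log2(mean noncore / mean core)`, and a switch call when the
  non-core enrichment changes by ≥ 2ε across the switch.
- **Border transposon induction** — median log2 fold change of
  transposon-flagged genes within a window of the core/non-core borders,
  with a one-sided rank-sum p and a label-permutation p (exhaustive when
  feasible).
- **Expression programs** — upper-quartile-scaled RPKM
  (`count / (kb × millions of reads)`, rRNA masked), the prominent top-half
  gene universe, switch fold changes `log2((post + 0.5)/(pre + 0.5))` and
  the >2-fold changed fraction, Pearson complete-linkage clustering into
  exponential / transitional / stationary phase programs, and one-sided
  Fisher exact category enrichment with Benjamini–Hochberg correction.
- **Bottleneck statistics** — mRNA share of the top `q` fraction of genes,
  Gini coefficient, category suppression folds across the switch (raw and
  normalized routes), and a paired t-test of ribonuclease induction on
  log2 expression.
- **Degradome** — fragment-read filtering (20–50 nt, sense to transcribed
  regions), the per-gene degradation index
  `DI = log2((F + 0.5)/N_F) − log2((S + 0.5)/N_S)` comparing full-length
  (`F`) and fragment (`S`) libraries, median-centered relative DI with
  faster/neutral/slower classes at ±1 log2, genome-wide degradation
  shifts, stability-class enrichment (`2^(ΔmeanDI)` folds, rank-sum p),
  and browser-loadable relative-DI tracks.

All coordinates are 0-based half-open internally; GFF3/BED/bedGraph
conversions happen only at file boundaries, and origin-spanning intervals
on the circular chromosome are handled throughout.

## Worked example

A complete run on a small synthetic dataset (320 genes on a 400 kb
circular chromosome, seven timepoints spanning a switch at 51 h):

```r
library(switchtome)
cfg <- sim_config(seed = 7, genome_length = 4e5, n_genes = 320,
                  long_depth = 3e5, fragment_depth = 1.5e5)
res <- run_all(cfg, "demo_out", seed = 7)
res$summary
```

```
                          statistic       value
1                  changed_fraction  0.65822800
2                     noncore_shift -1.56741000
3                   switch_detected  1.00000000
4                       border_fold  6.87003000
5                     border_p_perm  0.00009999
6         transcribed_either_strand  0.70019500
7            transcribed_unstranded  0.70019500
8                 antisense_overall  0.03000000
9          median_strand_preference  0.73836500
10                    top1pct_share  0.38417000
11                             gini  0.86143200
12 translation_suppression_fold_raw  4.39554000
13                          rnase_n  4.00000000
14                  rnase_n_induced  3.00000000
15                          rnase_p  0.80639400
16                delta_median_DI -2.36897000
```

Reading the output: 66% of prominent genes change more than 2-fold across
the switch; the non-core macro-region drops by 1.6 log2 units relative to
the core region and the switch is detected; border transposons are induced
6.9-fold with a permutation p of 1e-4; antisense transcription is recovered
at exactly the injected 3%; the replichore-wide leading-strand bias shows
as a positive median strand preference; the top 1% of genes carry 38% of
the mRNA; and the median degradation index drops sharply at the switch
(global acceleration plus the mRNA bottleneck). At this small scale only 3
of the 4 simulated ribonucleases register as induced and the paired t-test
is underpowered — the full-scale conditions (2000 genes, 1e6 reads per
library) recover 20–23 of 24 with p < 1e-4.

`run_all()` also writes per-stage TSVs, bedGraph tracks and an md5
manifest into `demo_out/`; reruns with the same config and seed are
byte-identical. The same stages are available as individual functions
(`normalize_expression()`, `region_enrichment()`, `degradation_index()`,
...) and accept on-disk GFF3/BED/TSV inputs via `read_annotation()` and
`read_counts`-style helpers or a YAML config.

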