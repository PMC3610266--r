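---
title: "Methods: transcriptome topography across a bacterial metabolic switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome topography across a bacterial metabolic switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`switchtome` analyses strand-specific time-course RNA-seq of an
actinomycete batch culture passing through its metabolic switch: the
transition between primary growth and secondary metabolism, marked by
growth arrest and a genome-wide rearrangement of transcription. The
package works downstream of read alignment: its inputs are per-base
coverage tracks (bedGraph), per-gene count tables (TSV) for full-length
and degraded-fragment libraries, a GFF3 annotation, and a BED partition of
the circular chromosome into core and non-core macro-regions.

The analysis rests on a small set of assumptions:

- The chromosome is circular with a declared replication origin; when no
  terminus is annotated it is placed diametrically opposite, since
  replichore symmetry is the natural null. All interval arithmetic is
  0-based half-open and wrap-aware, so origin-spanning genes and
  coordinate rotations are handled exactly.
- Counts are proportional to transcript abundance times gene length;
  normalization is RPKM followed by between-library upper-quartile
  scaling (each library divided by its 75th percentile of nonzero values
  over the geometric mean of those percentiles). rRNA genes are removed
  before any quantity — including the quartiles and library sizes — is
  computed, because rRNA carry-over otherwise dominates both.
- Reads overlapping two genes are counted for every overlapping gene.
  Fractional assignment is deliberately out of scope; the rule is declared
  rather than inferred.

# Stage-by-stage procedure

## Genome topography

*Transcribed fraction.* Coverage tracks are pooled by summation; a
position is transcribed when pooled coverage reaches `min_cov` (default 1)
on either strand (stranded view) or in the strand sum (unstranded view).
The singleton fraction — expressed positions at exactly depth 1 — is a
saturation indicator: near-saturating sequencing leaves very few singly
observed nucleotides.

*Strand preference.* Each position belongs to a replichore; leading
coverage is plus-strand on the origin→terminus replichore and minus-strand
on the other. Bins report `P = (L − G)/(L + G)`, in [−1, 1], `NA` when
empty. The default bin is 10 kb — the macro-region scale; the statistic is
invariant under bin refinement wherever coverage is piecewise constant.

*Macro-region enrichment and switch detection.* For region `r` at
timepoint `t`, `E(r,t) = log2(m_r / m)` with `m_r` the mean normalized
expression (of genes, or of coverage bins assigned by majority label) in
`r` and `m` the genome-wide mean. Two estimators are reported for the
non-core repression across the switch:

- the change of `E(noncore)` itself, used for detection; and
- the change of the core-referenced contrast `log2(m_noncore / m_core)`,
  reported as `noncore_shift`.

The contrast is the right estimator of a non-core fold change because the
genome-wide mean is itself depressed when half the genome is repressed: a
true 4-fold repression of a region covering half the chromosome moves
`E(noncore)` by only `log2(0.25/0.625) ≈ −1.32` but moves the contrast by
exactly −2. A switch is called when `|ΔE(noncore)|` between the mean
pre-switch and mean post-switch timepoints reaches `2ε`, with `ε = 0.2`
log2 units — a change-based rule. A sign-based rule (enriched before,
depleted after) was considered and rejected: it presupposes pre-switch
non-core enrichment, which is a property of particular datasets rather
than of the repression phenomenon itself. `ε = 0.2` separates genuine
macro-region shifts from binning noise at typical depths while remaining
far below the injected effect sizes.

*Border induction.* The test statistic is the median log2 fold change
(switch vs pre-switch, pseudocount 0.5) of transposon-flagged genes whose
midpoint lies within 5 kb of a core/non-core border. Because the
distribution of a median of a flagged subset is awkward analytically, two
p-values are reported: a one-sided rank-sum test against all other genes,
and a label-permutation p. The permutation test enumerates all
`choose(n, k)` subsets exactly whenever that count does not exceed
`n_perm`, and otherwise Monte-Carlo samples with the `(1 + hits)/(1 + n)`
estimator.

*Antisense and ncRNA candidates.* Antisense fraction is antisense
base-coverage over total base-coverage within gene bodies, overall and per
relative-position decile oriented 5'→3'. Intergenic ncRNA candidates are
maximal same-strand runs of positions with per-million normalized coverage
≥ 1 in at least one long library and no same-strand gene overlap; runs
separated by < 20 bp merge, lengths outside [50, 1000] nt are dropped, and
a candidate is "supported" when fragment libraries cover at least half of
it. Structure- and conservation-based scoring is out of scope.

## Expression programs

The analysis universe is the prominent set: the top half of genes ranked
by maximum normalized expression over the time course (ceiling at odd
counts, boundary ties broken lexicographically so the set is
deterministic). Maximum rather than mean prominence is used so that
transiently induced genes are retained — this is an assumption, recorded
here.

Fold changes use a 0.5-RPKM pseudocount, symmetric and standard for
shrinking low-expression ratios. The changed fraction is the proportion of
prominent genes beyond 2-fold between the last pre-switch timepoint and
the switch timepoint (both configurable).

Clustering operates on per-gene standardized `log2(RPKM + 0.5)` profiles
with distance `1 − Pearson` and complete linkage; constant profiles are
excluded with a warning since their correlation is undefined. The tree is
cut into three groups by default and each cluster is phased by its
centroid's argmax timepoint: pre-switch → exponential, switch →
transitional, post-switch → stationary. Finer panels are available by
raising `k`.

Category enrichment is a one-sided Fisher exact test per flat category
label against the universe, Benjamini–Hochberg adjusted. BH is the
package's choice of multiple-testing correction; the fold enrichment is
`(a/(a+b)) / ((a+c)/N)` on the 2×2 table.

## Bottleneck

Concentration statistics sort normalized expression at one timepoint and
report the share of the top `ceil(q·n)` genes and the Gini coefficient of
the Lorenz curve. Category suppression reports
`sum(category at pre)/sum(category at switch)` on two routes: raw counts,
which see genome-wide depletion through the realized library yield, and
normalized values, which only see composition changes (whether "counts"
means raw or normalized is genuinely ambiguous for such claims, so both
are emitted). The ribonuclease induction test is a paired t-test on
`log2(RPKM + 0.5)` across the flagged set; the default is two-sided —
conservative, since the direction could be asserted but is not —
and zero-variance differences return a degenerate flag rather than a
meaningless p of 0.

## Degradome

Fragment reads are filtered to 20–50 nt and to lying fully within
transcribed regions (per-million coverage ≥ 1 in a matched long library)
on the same strand; antisense reads are excluded as putative bona-fide
regulatory RNAs rather than degradation products. The 20–50 nt window is
the analysis default; the physical size selection of such libraries is
sometimes quoted as 15–50 nt, so the window is a configuration value.

The degradation index is
`DI = log2((F + 0.5)/N_F) − log2((S + 0.5)/N_S)`, full-length
representation over fragment representation, per-million normalized so
that DI is comparable across timepoints of different depths. Gene length
does not enter: it cancels provided fragment capture is proportional to
transcript length, which is assumed and recorded. Genes with fewer than 10
full-length reads are masked — DI is unstable near zero expression.
Relative DI subtracts the per-timepoint median over unmasked genes (so its
median is 0 by construction), and classes are called at ±1 log2 unit.
Class-level stability uses `2^(mean ΔrelativeDI)` folds with a two-sided
rank-sum test — a t-test was rejected because DI distributions are
heavy-tailed at low counts.

One identifiability caveat is intrinsic: per-million normalization cancels
any purely genome-wide rate change, so a *global* degradation shift is
only measurable against an external anchor. The package anchors DI to the
nominal (configured) library depths when they are recorded in the library
metadata, and the generator scales the realized fragment yield with total
degradation flux, mirroring the fact that a degrading transcriptome
physically yields more fragment material. Real experiments would need
spike-ins or careful yield accounting for this quantity; relative (gene-
and class-level) statements are unaffected.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with ground truth for every injected effect:

- a 2 Mb circular chromosome with 2000 non-overlapping genes (~900 bp,
  about one gene per kb — the coding density of an actinomycete genome at
  this gene count), split half-and-half into contiguous core and non-core
  regions;
- 20 transposon genes clustered within 5 kb of the two region borders;
  one gene in 80 (up to 24) flagged ribonuclease; 4 rRNA genes; 12
  functional categories drawn with region-biased frequencies (core
  enriched for housekeeping, non-core for secondary/adaptive functions);
- 75% of genes on the leading strand of their replichore;
- log-normal base expression (sdlog 1.75, which puts the expected top-1%
  mRNA share near 0.25–0.30);
- seven timepoints (28–93 h) with the switch at 51 h; 30% "pre" and 30%
  "post" program genes with graded trajectories (multipliers 1→0.3→0.1 and
  0.1→0.5→1 around the switch) so programs change *at* the switch while
  their expression peaks lie strictly before/after it; non-core repression
  (−2 log2) strictly after the switch; transposon (+3) and ribonuclease
  (+2) spikes at the switch only;
- a global bottleneck scaling all expected counts by 0.4 at the switch;
  negative-binomial count sampling (dispersion 0.1; dispersion 0 gives
  deterministic rounded expectations); deterministic coverage synthesis
  spreading each gene's reads over its body with a 3% antisense leak whose
  weight doubles linearly over the 3' third;
- per-gene degradation-rate heterogeneity, log-normal with 1.5 log2 units
  of spread (bacterial mRNA half-lives span roughly 1–40 min), with class
  shifts (ribosome-related 4× faster, transcription factors 2× slower
  from the switch on) and a genome-wide 2× acceleration at the switch;
  fragment libraries are multinomial with yield proportional to
  degradation flux.

Continuous rate heterogeneity is a deliberate design choice: with rates
tied at 1 for all unlisted genes, rank-based recovery of the rate ordering
is bounded far below 1 by midrank ties no matter how good the estimator
is, which would make rank correlation useless as a recovery diagnostic.

Randomness is two-level: structural draws and count-level sampling use
independent sub-seeds, so count matrices can be resampled over a fixed
structure — this is what the calibration tests do.

What the generator does **not** emulate: operon structure and co-directional
run-length correlations, sequencing error and GC bias, read-level
placement noise within gene bodies (coverage is expected, not sampled, so
saturation metrics behave more smoothly than on real data), plasmids, and
condition-dependent category–program coupling (programs are assigned
independently of category and region). Passing recovery tests therefore
demonstrates the estimators' correctness under the declared statistical
structure, not robustness to every artefact of real libraries.

# Numerical choices and degenerate inputs

- Pseudocounts: 0.5 throughout (fold changes, DI, log-profiles).
- Ties: prominence and boundary ties break lexicographically; permutation
  tail comparisons use a 1e-12 slack so exact-equality statistics count as
  hits; Fisher p is the hypergeometric tail (`phyper`), checked against an
  explicit binomial-coefficient summation to 1e-10 relative error.
- Degenerate inputs: all-zero libraries, empty regions, zero-variance
  paired differences, unstranded input where strandedness is required, and
  mismatched gene sets all raise informative errors (or flags) rather
  than propagating NaN.
- bedGraph output merges adjacent equal bins, omits missing values and
  prints 6 significant digits; TSV output keeps `NA` explicit.

# Problem sizes used by the test suite

Unit tests run on toy inputs and a 400 kb / 320-gene simulation. Recovery
tests run once at the full default conditions (2 Mb, 2000 genes, 1e6-read
long libraries, 5e5-read fragment libraries). Calibration tests resample
counts 1000 times over a fixed 600 kb / 400-gene structure at 2e5-read
depth — null calibration does not depend on problem size, and this keeps
the suite fast. Exhaustive oracles (Fisher tables, permutation subsets,
linkage trees) run at the largest sizes where complete enumeration is
practical (margins ≤ 16 plus randomized larger tables; 20 genes choose 5;
8-gene trees).

# Known limitations

- The border-induction test conditions on the annotated border positions;
  uncertainty in the partition itself is not propagated.
- Upper-quartile scaling assumes most genes are not changing; across this
  particular switch that is only approximately true, which is why
  bottleneck-scale statements use the raw-count route.
- The ncRNA candidate caller is presence/size-based only; coding
  potential and secondary structure are out of scope.
- DI compares libraries of different chemistry; library-preparation
  selectivity (5' phosphorylation state) is an experimental property the
  index cannot correct for.
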