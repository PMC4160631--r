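---
title: "Methods: stress-responsive small RNA classification and factorial expression analysis"
author: "stressSmallRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-responsive small RNA classification and factorial expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressSmallRNA)
```

## The problem this package addresses

Trans-acting siRNAs (ta-siRNAs) are 21 nt phased small RNAs processed from
*TAS* precursor transcripts after miRNA-guided cleavage; the TAS3-derived
subfamily targets the auxin response factors *ARF2/3/4*. In *Arabidopsis*,
abiotic stress (drought, cold, high salinity) shifts the small-RNA
population: ta-siRNA families drop, and sense-strand mRNA degradation
fragments accumulate. Detecting these shifts from pooled smRNA-seq
libraries, and relating them to genotype x treatment expression changes in
flower buds of ta-siRNA-deficient (*rdr6*) versus wild-type plants, requires
a chain of small, well-specified computational steps. This package
implements that chain as tested, reusable functions, together with a
synthetic-data module that generates every input with known ground truth so
each step — and the pipeline end to end — can be validated without any
external download.

## Small-RNA analysis model

1. **Length selection and collapsing** (`collapse_signatures`). Reads of
   17–30 nt are kept (the size range captured by the library protocol) and
   collapsed to unique *signatures* with per-library counts. A *singleton*
   is a signature with total count 1 over all libraries.
2. **Exact mapping** (`map_exact`). Every perfect-match occurrence of a
   signature on the plus strand, and of its reverse complement (reported as
   a minus-strand hit), on every chromosome. No mismatches: the analysis is
   defined on perfectly matched positions only. Internally this uses
   Biostrings preprocessed dictionaries grouped by read length; the test
   suite checks equivalence with a naive both-strand substring scan.
3. **Structural-RNA elimination** (`filter_structural`). A signature with
   *any* hit overlapping a tRNA/rRNA/snoRNA/snRNA feature (either strand,
   >= 1 nt overlap) is removed. The any-hit rule is deliberately
   conservative: it prevents abundant structural fragments from leaking
   into intergenic or gene-derived categories via secondary hits.
4. **Locus grouping** (`cluster_loci`). Hits separated by a gap of
   *less than* 150 nt are merged into one locus (single linkage,
   strand-agnostic). The boundary is strict: a gap of exactly 150 nt keeps
   two loci separate. With 1-based closed intervals the gap equals the
   IRanges gap width, so `reduce(min.gapwidth = 150)` implements the rule
   exactly; tests compare against a brute-force transitive closure.
5. **Classification** (`classify_signatures`). Each signature receives one
   category by precedence over all of its hits:
   miRNA > ta-siRNA > protein-coding sense > protein-coding antisense >
   TE gene > pseudogene > intergenic TE > other intergenic.
   Dedicated small-RNA loci outrank genes so that composition wedges are
   mutually exclusive; a multi-mapping signature is counted once, in its
   highest-precedence category. (Counting once per locus instead would be
   the main alternative; it is isolated behind this one operation.)
6. **miRNA-total normalization** (`normalize_by_mirna`). Stress shifts the
   amount of mRNA degradation, so library size is a biased denominator.
   Family counts are divided by the library's total miRNA count (raw ratio,
   no extra scaling) and expressed relative to the nonstressed control.
   A zero control count yields an undefined (NA) relative value, never
   infinity.
7. **Enrichment testing** (`hypergeom_enrichment`, `enrich_families`). Each
   (family, stress library) pair is tested with exact hypergeometric tail
   sums `p_up = P(X >= k)` and `p_down = P(X <= k)` — `stats::phyper`, no
   normal approximation — and flagged when the tail is strictly below
   `alpha = 1e-3`. The 2x2 margins use the miRNA pool as reference counts:
   for a miRNA family (a subset of that pool), `k` is the family count in
   the stress library, `n` the library's miRNA total, and `K`, `N` the
   pooled stress+control analogues. A ta-siRNA family is not contained in
   the miRNA pool, so its population is unit + miRNA reads
   (`n = k +` miRNA total, `N = K +` pooled total); this keeps
   `k <= min(n, K)` and both margins consistent for every family kind. The
   margin construction is a documented choice confined to one operation, so
   alternatives are swappable.

## Factorial expression analysis

The expression side models a balanced 2 genotypes (WT, *rdr6*) x 2
treatments (nonstressed, drought) design with >= 2 (default 3) replicates
per cell.

- **Normalization** (`percentile75_normalize`): each array is divided by its
  own 75th percentile, using the linear-interpolation quantile (type 7) so
  results are bit-reproducible; afterwards every array's 75th percentile is
  exactly 1.
- **Per-gene two-way ANOVA** (`two_way_anova`): genotype + treatment +
  interaction fitted on log2 intensities. The replicated 2x2 design
  supports the interaction term, but significance calls use the two
  main-effect q-values only (the contrasts of interest are *rdr6* vs WT
  and drought vs nonstressed). The log2 transform matches the scale of the
  ratio axes below; the fit uses closed-form balanced-design sums of
  squares vectorized over all genes, which makes many-replicate simulations
  cheap; `stats::aov` serves as the independent oracle in the tests. Zero
  residual variance is flagged degenerate (p = NA) instead of propagating
  NaN.
- **Multiplicity** (`bh_fdr`, `anova_fdr`): Benjamini–Hochberg step-up
  per factor across genes, flags at FDR < 0.075 (strict).
- **Ratio pairs** (`genotype_treatment_ratios`): per gene,
  `x = log2((rdr6-NS + rdr6-D) / (WT-NS + WT-D))` and
  `y = log2((WT-D + rdr6-D) / (WT-NS + rdr6-NS))`, where each term is a
  replicate cell mean computed before summing. Swapping genotype labels
  negates `x` and leaves `y` unchanged.
- **GO-set correlation** (`go_scatter_r2`): squared Pearson correlation of
  `(x, y)` over a gene set (>= 3 usable members), with the correlation sign
  reported; zero variance on an axis is reported as undefined.
- **Coexpression screen** (`coexpression_screen`): Pearson correlation with
  each anchor gene (default *ARF3*, *ARF4*) across >= 10 conditions,
  two-sided t-test, requiring p < 0.01 *and* r > 0 for **both** anchors.
  The positive-sign requirement and the anchor intersection are package
  choices; the threshold alone would also admit strong negative
  correlations.
- **Promoter scanning** (`scan_promoter_motif`): up to 1000 nt upstream of
  the annotated gene start on the gene's strand, case-insensitive search
  for the motif (default TGTCTC, the AuxRE core) and its reverse
  complement, since cis-elements act on either strand; `both_strands =
  FALSE` preserves the narrower sense-only reading. Offsets are 0-based
  from the window's 5'-most base. "Gene start" means the annotated feature
  start (the toy annotation does not model UTRs, so feature start stands in
  for the start codon).
- **Relative quantification** (`delta_delta_ct`): `2^-(ddCt)` against a
  reference gene (U2 for small RNAs, ACT2 for mRNAs in the motivating
  assays) and a calibrator sample.

## What the synthetic-data module emulates

`generate_genome` places non-overlapping typed features (10 categories,
including the four structural-RNA classes) on uniform-random chromosomes —
default 2 x 200 kb, large enough to hold all categories with a 1100 nt
clearance (every gene keeps a free 1 kb promoter; distinct features cannot
merge under the 150 nt gap rule) yet small enough for exact mapping in
seconds. Each MIRNA locus stores one 21 nt mature sequence, each TAS locus
a phase start.

`simulate_smrna_libraries` draws each library multinomially at fixed depth
from locus emissions (class-level baseline weights times per-treatment
fold-change multipliers), plus two read classes the stress biology
requires: sense-strand degradation fragments of protein-coding genes
(default 15% of reads under drought/salt vs 5% in the control) and random
intergenic background (5%). TAS loci emit 21 nt reads on a fixed register
from the phase start; MIRNA loci emit their exact mature sequence; all
other origins draw lengths from a 17–30 nt distribution peaked at 21 and
24 nt, as in real plant smRNA libraries. Default fold changes put TAS at
0.3 under drought and salinity and 0.7 under cold — strong, unambiguous
downregulation for power checks. Because multinomial sampling renormalizes
after fold changes are applied, the realized count ratio of a downregulated
class is slightly below the nominal multiplier when the class holds a
non-negligible share of the library; tests therefore compare ratios within
binomial sampling bounds rather than exactly.

`simulate_expression_matrix` generates
`2^(baseline + g*x_g + t*x_t + i*x_g*x_t + noise)` with indicator coding,
so a +1 log2 genotype effect doubles the *rdr6* cells. GO sets draw their
(genotype, treatment) effect pairs from a bivariate normal with a planted
correlation rho; the correlation is planted on *true* effects, so the
observed R-squared of the ratio pair shrinks with noise and with finite set
size — the tests allow for this attenuation explicitly rather than asserting
exact recovery.

What the generator does **not** emulate: 454 homopolymer and base-calling
errors, adapter artifacts, the miR173/miR390 cleavage biochemistry that
positions real phase registers, probe-level microarray effects, or
genome-scale sequence composition. Passing tests therefore demonstrate that
the *algorithms* recover planted structure under clean sampling noise, not
that the defaults match any particular organism's empirical distributions.

## Numerical choices and degenerate inputs

- Coordinates are 1-based closed (`GRanges`) internally; BED export
  converts to 0-based half-open, GFF3 stays 1-based closed. Conversions are
  tested.
- All significance thresholds are strict (`<`): a p-value of exactly 1e-3,
  or a q-value of exactly 0.075, is not flagged.
- Quantiles use type 7 (linear interpolation), the R default, fixed for
  reproducibility.
- Empty inputs are reported, not guessed: an empty library yields a flagged
  all-zero composition row; an empty signature set reports an undefined
  singleton fraction; sub-3-gene GO sets report NA with a reason.
- Every generator is a pure function of its spec, including the seed;
  the pipeline derives stage seeds from the master seed by fixed offsets,
  and identical configuration yields byte-identical report bundles.
- Placement of features uses bounded rejection sampling (500 tries) and
  fails naming the crowded category rather than degrading silently.

## Problem sizes

The default test and pipeline configurations are desk-scale by design: a
2 x 200 kb genome, 2e4 reads per library for power checks (1e4 in the
planted-recovery simulations), 2000-gene factorial matrices with 20
simulation replicates for the error-control checks, and 300–1000-gene GO
sets for correlation recovery. Planted GO sets are always embedded in a
matrix of mostly unaffected genes: a set spanning the whole matrix would
shift the per-array 75th percentiles and let the scaling step distort the
ratio pairs (the same global-scaling assumption discussed under
limitations). The acceptance script uses 20,000-member sets inside
100,000-gene matrices so the Monte-Carlo error of the recovered R-squared
is small against its reporting precision. These sizes keep a full run in
seconds while leaving all statistical conclusions comfortably inside their
tolerance bands.

## Known limitations

- Exact matching only; a single sequencing error unmaps a read. This is
  faithful to the analysis being mirrored but unsuitable for error-prone
  platforms without prior correction.
- The hypergeometric margins condition on the miRNA pool; other defensible
  2x2 constructions (e.g. family vs all mapped reads) would shift p-values.
  The construction is isolated in `enrich_families`.
- Families are defined by annotated MIRNA/TAS loci; the package does not
  discover novel phased loci (no phasing score), and does not predict
  miRNA targets.
- Quantile-scaling normalization (75th percentile, like any global scaling)
  assumes that differential expression is sparse or sign-balanced around the
  scaling quantile. When a large, one-directional block of genes is
  differentially expressed, the affected arrays' 75th percentiles shift and
  normalization induces an apparent opposite shift in every unchanged gene,
  inflating false discoveries downstream. The error-control simulations
  therefore plant sign-balanced effects and measure the ANOVA + BH chain on
  intensities that already share a common scale (the generator plants no
  array-scale effects, so the scaling step is a no-op by construction and
  is validated by its own idempotence/scale-invariance tests).
- The coexpression screen is validated on synthetic compendia only; with
  only 12 conditions the t-test on r is coarse, and real compendia with
  hundreds of conditions will behave differently.

## A worked example

```{r example, eval = FALSE}
cfg <- default_pipeline_config(seed = 7)
report <- run_pipeline(cfg, outdir = "run7")
print(report)
```

The printed report shows the per-library Table-style summary (sequences
after filters and loci), the singleton fraction, enrichment calls, the
Venn partition of differentially expressed genes, planted-versus-observed
GO-set R-squared values, and the coexpression and motif counts, all
recomputed from the synthetic data generated under the given seed.
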