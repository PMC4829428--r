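---
title: "Counting and testing early-embryo transcriptomes with mztseq"
author: "mztseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and testing early-embryo transcriptomes with mztseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mztseq)
```

# The problem

At the maternal-to-zygotic transition (MZT), the mouse embryo switches from
maternally deposited transcripts to its own newly transcribed genome,
normally at the 1- to 2-cell stage. Two features make bulk or single-embryo
RNA-seq of this window statistically awkward:

* **Repeat-derived transcription.** Zygotic genome activation transcribes
  retrotransposon families (LINE-1, SINE, MT/MERVL elements) whose reads map
  equally well to hundreds or thousands of genomic copies. Discarding
  multi-mapped reads discards the signal of interest.
* **Tiny designs.** Embryo experiments typically have two or three
  biological replicates per condition, too few for stable per-gene variance
  estimation.

`mztseq` implements an analysis pipeline for this setting: a unified gene +
repeat-family annotation, multi-mapping-aware weighted counting, a
Monte-Carlo negative-binomial (NB) test for differential expression with a
dispersion-mean trend used as a per-feature floor, and the downstream MZT
read-outs — activated/repressed tallies, sample dendrograms, principal
components and standardized heat-map matrices. A synthetic-data module
generates all of these inputs with known ground truth, so the full pipeline
is testable without sequencing data.

# The feature model

Two kinds of features are counted against:

* a **gene locus** is the union of exon intervals of all transcripts
  sharing a `gene_id` (redundant transcripts — identical exon chains on the
  same strand — are collapsed first);
* a **repeat family** is the set of all genomic copies sharing one
  RepeatMasker repeat name, collapsed under a single feature id, so that a
  read hitting many same-name copies still hits *one* feature.

Coordinates are stored 1-based closed; the UCSC `rmsk` table dump (0-based
half-open) is converted on read. A repeat name that collides with a gene id
receives a `repeat:` prefix. Where several gene catalogs have been merged
upstream, loci are keyed by `gene_id` alone; no overlap-based reconciliation
is attempted, since the locus key is exactly what the counting rule uses.

# Weighted counting of multi-mapped reads

For one read with a set of equally best alignments, let $N_g$ be the number
of *distinct gene loci* and $N_r$ the number of *distinct repeat names* its
alignments overlap (an alignment counts when it overlaps a feature interval
by at least a fraction `minOverlap`, default 0.5, of its length; strand is
ignored, matching a non-strand-specific amplification protocol). Each gene
locus receives weight $1/N_g^2$ and each repeat name $1/N_r^2$. The total
mass a read leaves in a table is therefore $1/N$: a unique read contributes
a full count, and the contribution of ambiguous reads decays quadratically
with their promiscuity. The two tables are computed independently — a read
spanning a gene and a repeat contributes to both with its own $N$ each;
whether such a read should instead split its mass across tables is not
decidable from the counting rules alone, and the independent reading is the
one that preserves both rules exactly.

The quantifier accepts name-grouped SAM/BAM (one file per sample) or an
alignment-free hit table (`read_id`, `sample_id`, `feature_id`), and the
synthetic module's `simulateAlignmentHits()` produces hit tables together
with a brute-force per-read oracle matrix, computed by independent
enumeration, against which `countAlignments()` is tested for exact
agreement.

# The differential-expression model

Counts are modeled as NB with variance $\mu + \alpha\mu^2$ ($\alpha = 0$ is
Poisson). The test of a feature between conditions $A$ and $B$ proceeds:

1. **Filter.** A feature is tested only if its mean *raw* count reaches
   `minRawCount = 10` in at least one of the two conditions. The filter is
   condition-level (not per-sample) because replicate numbers are small.
2. **Normalization.** Median-of-ratios size factors on the two-condition
   submatrix, rescaled to geometric mean 1; a per-sample median-of-nonzero
   fallback covers matrices in which no feature is positive everywhere.
3. **Dispersion.** Per-feature method-of-moments estimate
   $\hat\alpha = \max\{0, (s^2 - \bar\mu)/\bar\mu^2\}$ from the pooled
   within-condition variance, then a trend
   $\alpha(\mu) = a_0 + a_1/\mu$ fitted by non-negative least squares over
   features with positive mean and dispersion. The trend is used as a
   **floor**: the effective dispersion is
   $\alpha_{\mathrm{eff}} = \max\{\hat\alpha, \alpha(\mu)\}$, guarding the
   test against underestimated variance at 4 residual degrees of freedom.
4. **Monte-Carlo null.** Under the null of zero fold change, both
   conditions share the pooled mean $\mu$. Each of `iterations = 1000`
   iterations draws $n_A + n_B$ NB$(\mu, \alpha_{\mathrm{eff}})$ counts,
   averages them within conditions, and records
   $\log_2\frac{\bar{x}_B + c}{\bar{x}_A + c}$ with pseudocount $c = 1$.
   For equal-$n$ designs the two blocks are exchangeable, so the simulated
   sample is mirrored around zero; this pins the null mean at its exact
   value 0 and makes swapping the conditions negate $z$ while leaving
   p-values identical. The observed log fold-change (same formula on the
   observed normalized condition means) is standardized by the simulated sd
   and translated to a two-tail p-value via the standard normal, since the
   simulated distributions are normal to good approximation.
5. **Correction.** Gene loci and repeat families are pooled into a single
   Benjamini-Hochberg correction; significance is adjusted p `< 0.05`.

Reproducibility is part of the contract: every feature's Monte-Carlo stream
is derived deterministically from the root seed and the feature's position,
so results do not depend on iteration order.

```{r de-example}
sc <- mztScenario(seed = 1)
de <- runDifferentialExpression(sc$counts, "oocyte", "wt2C",
    deConfig(iterations = 300, seed = 1))
classifyComparison(de)
```

## Calibration properties

On pure-null simulations at the reference conditions (2000 features, means
log-uniform in 20–2000, trend $0.05 + 2/\mu$, $n = 3$ per condition) the
raw p `< 0.05` fraction runs at about 0.03–0.04 and BH at 0.05 makes
essentially no false discoveries. The mild conservatism is intrinsic to the
dispersion floor: with 4 degrees of freedom the moment estimate scatters
widely, and `max(obs, trend)` can only inflate the simulated null sd, never
deflate it. Supplying the true dispersion instead restores near-nominal
behavior (~0.055 in the same experiment); the floor trades a little power
for protection against variance underestimation, which is the sensible side
to err on for $n = 3$ embryo designs. On the reference truth-bearing
scenario (20% activated, 20% repressed at 4–16-fold) sensitivity is ≈0.99
with empirical FDR ≈0.01–0.02.

# Downstream MZT read-outs

All downstream analyses run on `log2(normalized + 1)` expression.

* **Activation/repression tallies** (`classifyComparison()`): significant
  features with positive log fold-change are "up" in the second condition
  (zygotically activated when comparing oocyte → 2C), negative are "down"
  (maternally repressed); gene loci and repeat families are tallied
  separately. Swapping the comparison exchanges the tallies exactly.
* **Sample dendrogram** (`hierarchicalClusterSamples()`): correlation
  distance ($1 - r$ across features) with average linkage — the standard
  transcriptome-dendrogram choice; both are config-exposed since the
  display itself fixes neither. Columns are sorted by sample id first, so
  tied merges resolve deterministically. Exported as newick with merge
  heights as node heights.
* **PCA** (`principalComponents()`): samples are observations on
  per-feature-centered, *unscaled* log expression — per-feature scaling is
  deliberately reserved for the heat-map display, which standardizes
  separately. Component signs follow a deterministic convention (the
  largest-magnitude loading of each component is positive). A rank-1
  configuration (e.g. two identical samples plus one distinct) is valid and
  yields PC1 variance fraction 1; only a completely degenerate matrix (all
  samples identical) errors.
* **PC1 gene set** (`selectPc1Features()`): features with
  $|{\rm loading}_1| > k \cdot {\rm sd}({\rm loading}_1)$, default
  $k = 2$. "Strongly associated with PC1" admits many formalizations; a
  loading-sd threshold is deterministic, scale-free and testable.
* **Heat-map matrix** (`standardizedHeatmap()`): each selected feature is
  standardized to mean 0 and sample sd 1 (denominator $n-1$), making the
  color scale relative to each feature's own mean and variance; rows are
  ordered by average-linkage clustering of the standardized rows
  (Euclidean distance — on standardized vectors this is monotone in
  correlation distance). Zero-variance rows are dropped with a warning.

```{r analysis-example}
expr <- logTransform(sc$counts)
cl <- hierarchicalClusterSamples(expr)
cl$newick
pca <- principalComponents(expr)
round(pca$varianceFraction, 3)
```

# What the synthetic data emulate

`makeTruth()` + `simulateCountMatrix()` generate a three-condition design —
oocyte, wild-type 2-cell (`wt2C`), maternal-mutant 2-cell (`mut2C`) — with:

* NB counts whose dispersion follows the declining trend
  $\alpha(\mu) = a_0 + a_1/\mu$ (defaults $0.05 + 2/\mu$, a typical
  low-input trend shape: strong extra-Poisson noise for weakly expressed
  features, asymptotic biological CV $\sqrt{a_0} \approx 22\%$);
* zygotically activated and maternally repressed classes (defaults: 20%
  each, fold changes log-uniform over 4–16-fold, baseline means log-uniform
  over 20–2000 — large enough to pass the raw-count filter while spanning
  the dispersive low end);
* a **failed-MZT mutant** whose condition means are the mixture
  $\lambda \cdot \text{oocyte} + (1-\lambda)\cdot \text{wt2C}$ with default
  $\lambda = 0.8$: the mutant retains maternal transcripts and largely
  fails zygotic activation. As $\lambda \to 1$ the mutant becomes
  oocyte-like; the mutant-to-oocyte cophenetic distance in the sample
  dendrogram decreases monotonically in $\lambda$, and at $\lambda = 0.8$
  mutant 2C embryos cluster with oocytes rather than with wild-type 2C —
  the failed-transition topology;
* multi-mapped alignment-hit tables with breadth $N$ drawn from a
  configurable profile (default mass on $N \in \{1,2,3,5\}$) plus the
  brute-force counting oracle.

The reference problem sizes (2000 genes + 100 repeat families, $n = 3$ per
condition, 1000 Monte-Carlo iterations) are chosen to make calibration
estimates stable while a full simulate–count–test–cluster cycle stays well
under a minute on one core.

What the generator does **not** emulate: positional read structure inside
features (hits are simulated at the feature level), alignment and
sequencing error, amplification distortion of low-input libraries,
correlated fold changes among co-regulated genes, and library-composition
bias beyond scalar size factors. Passing tests therefore demonstrate the
statistical machinery is correct under its own model assumptions — not that
those assumptions capture every pathology of real embryo libraries.

# Numerical choices and edge cases

* NB parameterization is (mean, dispersion) everywhere, with a single
  conversion to R's `(size = 1/alpha, mu)`; $\alpha \le 0$ degenerates to
  Poisson draws. This eliminates simulator/test parameterization
  mismatches.
* The trend fit clamps $a_0, a_1 \ge 0$ by comparing the unconstrained
  least-squares fit with both boundary fits and keeping the best — exact
  for this two-parameter problem.
* A degenerate Monte-Carlo null (empirical sd 0) is floored at `1e-8` and
  flagged rather than dividing by zero.
* Features with zero pooled mean are recorded but not tested; untested
  features carry `NA` statistics and are never significant.
* The fallback size-factor path (no feature positive in all samples) warns,
  since median-of-nonzero normalization is cruder than median-of-ratios.
* `benjaminiHochberg()` delegates to `stats::p.adjust(method = "BH")`; the
  test suite checks it against an independently coded step-up oracle rather
  than re-implementing the adjustment in the package.

# Limitations

* The Monte-Carlo p-values are read from the fitted normal, so they are
  smooth below the empirical resolution $1/\text{iterations}$; extremely
  small p-values rest on the normality of simulated log fold-changes.
* The dispersion floor makes the test conservative at very small replicate
  numbers (see *Calibration properties*); users wanting nominal type-I
  behavior at larger $n$ can raise `iterations` and supply their own trend.
* The pipeline consumes alignments or hit tables; read trimming, quality
  filtering and alignment itself are upstream concerns.
* Counts are weighted, hence fractional: they are not suitable for exact
  count-based tests elsewhere without rounding decisions.
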