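---
title: "floraltc: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{floraltc: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`floraltc` analyses a dense time course of flower development measured
on two-channel common-reference microarrays, and ships a synthetic-data
generator that emulates the whole study so each stage can be validated
against a known ground truth. This vignette documents the statistical
models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not demonstrate.

## The measurement model

Every array co-hybridizes one sample against a common reference pooled
from all time-points, so the quantity carried through the pipeline is
the M-value, `M = log2(sample / reference)`, accompanied by the average
log2 intensity `A`. The common reference makes all arrays directly
comparable on the M scale. Preprocessing follows the standard
two-channel path:

1. **Background correction** by subtraction. Corrected intensities
   that are not strictly positive cannot be log-transformed; they
   become missing rather than being floored at a pseudo-count, which
   would fabricate extreme negative M-values.
2. **Within-array normalization**: a robust loess regression of M on A
   (span 0.3, tricube weights, 4 robustifying iterations; built on
   `limma::loessFit`) removes intensity-dependent dye bias. The span
   is exposed because the appropriate smoothness depends on the bias
   shape; 0.3 tracks the slowly varying dye effects typical of these
   arrays without chasing noise.
3. **Between-array normalization**: quantile normalization of the
   A-values only (each quantile replaced by its cross-array mean, tied
   ranks averaged; `limma::normalizeQuantiles`). M-values are left
   untouched — the log-ratios are already comparable under the common
   reference, and only the intensity scale needs alignment.
4. **Summarization**: probes averaged per gene; a gene is missing on
   an array only when all its probes are.
5. **Expression filter**: per array, the threshold is the median
   A-value of the negative-control probes; a gene is kept if it beats
   the threshold on at least `min_arrays` arrays (default 1 — a gene
   must exceed background somewhere to be interpretable anywhere).
   The threshold is deliberately per-array and on the A scale, since
   background level varies by array and M is uninformative about
   absolute abundance.

## Differential expression

### The moderated linear model

For gene *g* the model is a one-way layout on time-point: the
coefficient at each time-point is the replicate mean of M, and the
residual variance `s2_g` has `d_g` degrees of freedom (arrays minus
time-points observed). With 3 replicates, `d_g` is small and raw
per-gene variances are unstable, so they are moderated by empirical
Bayes. Under a scaled inverse-chi-square prior with scale `s0^2` and
degrees of freedom `d0`, the posterior variance is the precision-
weighted compromise

```
s2_post = (d0 * s0^2 + d_g * s2_g) / (d0 + d_g)
```

The hyperparameters are estimated by moment matching on
`e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`: the mean of `e`
identifies `s0^2` and its variance in excess of the chi-square
sampling component `trigamma(d_g/2)` identifies `d0` through trigamma
inversion (a Newton iteration). When the observed spread of `e` does
not exceed the sampling component the data carry no evidence of
variance heterogeneity; `d0` is reported infinite and every posterior
variance equals `s0^2`. Genes with `s2_g = 0` are excluded from
hyperparameter estimation (their log-variance is undefined) but still
receive a posterior variance. On hierarchical simulations with
`d0 = 4, s0^2 = 0.05, d_g = 20` and 5,000 genes the estimates land
within a few percent of the truth, and the implementation agrees with
the established `limma::squeezeVar` to numerical precision — that
agreement is checked in the test suite, where `squeezeVar` serves as
an independent cross-check, never as the implementation.

One subtlety: when all observed `s2_g` are identical, the estimator
reports `s0^2 = exp(mean(e))`, which exceeds the common value by the
log-scale sampling correction `exp(log(d/2) - digamma(d/2))` (about
5 % at `d = 20`). This is the behaviour of the standard moment
estimator — observing identical variances is itself inconsistent with
chi-square sampling noise, and the estimator prices that in.

### The global F-scan and the windowed contrasts

Two questions are asked in sequence. *Does the gene change at all?*
A moderated F-statistic (between-time-point mean square over
`s2_post`, with `n_tp - 1` and `d_g + d0` degrees of freedom) is
BH-adjusted across genes; genes below 0.01 are "responsive". In a
dense developmental course this flags the large majority of the
transcriptome, because slow drift in organ size and composition moves
almost everything. *Does it change quickly?* All contrasts between
time-points at most 2 days apart (inclusive, on the real day values of
the design) are tested with moderated t-statistics

```
t = (coef_j - coef_i) / (s2_post^0.5 * sqrt(1/n_i + 1/n_j))
```

with `d_g + d0` degrees of freedom (the normal reference when `d0` is
infinite). All gene-by-contrast p-values are pooled into a single BH
adjustment — the adjustment is "across the experiment", which is the
stricter and simpler reading; a per-contrast option exists but is not
the default. A gene is called differentially expressed when some
windowed contrast has adjusted p below 0.01 **and** fold change of
1.7 or greater (inclusive). The fold change is measured on the fitted
contrast coefficient, i.e. `2^|coef_j - coef_i|`: the fitted
difference of replicate means is the quantity actually tested, so
thresholding anything else would let the significance and effect-size
filters disagree about the same contrast.

On planted simulations (2,000 genes, 14 time-points, 3 replicates,
30 % differentially expressed, 20 seeds) the realized false-discovery
proportion stays below 0.05 and genes whose true profile moves at
least 1.5 log2 units within some 2-day window at residual SD ≤ 0.25
are recovered in more than 90 % of cases.

## Co-expression clustering

Profiles are replicate-averaged per time-point and z-scored across
time-points, so clustering sees only temporal *shape*, not amplitude.
Constant profiles cannot be scaled and are dropped with a warning.
K-means uses Euclidean distance with k-means++ style seeding and 25
restarts, keeping the best fit by within-cluster sum of squares;
labels are arbitrary, so they are relabelled 1..k by descending size
for stable output, and all comparisons against planted truth use the
label-invariant adjusted Rand index. The elbow curve reports BSS/TSS
over a k range and suggests the point of maximum perpendicular
distance to the chord joining the curve's endpoints — but the
suggestion is advisory only and never applied silently; the number of
clusters in this kind of analysis is a judgement call, and
`kmeans_cluster` requires an explicit k (default 15).

## Tissue-atlas mapping

For each cluster gene covered by the atlas, the tissue groups holding
its maximum and minimum expression are tallied; percentages are
reported over covered, untied genes, and genes absent from the atlas
or tied at the extreme are counted separately rather than being
assigned arbitrarily. Atlas values are used exactly as supplied (no
re-normalization); whether they are on a log or linear scale is the
supplier's contract and does not affect argmax/argmin. Permuting atlas
columns never changes which tissue is reported.

## Resampling enrichment and the 3-SD rule

For each cluster of size `n_c`, the observed annotated fraction is
compared with the fractions of `n_iter = 100` random sets of `n_c`
genes drawn **without replacement** from a background universe —
without replacement because the random sets stand in for real
clusters, which never contain a gene twice. Two universes are run side
by side: the DEG list (is the layer concentrated in this cluster
relative to other dynamic genes?) and the whole array (relative to the
genome?). A cluster is flagged when its observed fraction lies beyond
3 standard deviations of the resampled mean, with the sign giving
enrichment versus depletion. The rule is kept as stated rather than
converted to a p-value; the z-score is reported alongside for users
who prefer thresholds. Degenerate nulls (zero SD, e.g. a saturated
annotation) are flagged as degenerate and never significant. The
Monte-Carlo null is validated against the closed-form hypergeometric
mean and SD, and with random annotations the rule fires in well under
2 % of cluster tests.

Bound-gene sets come from binding peaks through a strand-aware window:
a gene is bound if a peak overlaps the transcribed region extended
3 kb on the promoter side and 1 kb past the 3' end. All coordinates
are 0-based half-open (BED convention) throughout; windows are clipped
at zero; overlap is strict half-open overlap, so a peak abutting the
window boundary does not count. A peak may annotate several genes.

Term enrichment uses one-sided Fisher exact tests (enrichment is the
question the analysis asks; a two-sided option exists) with
Benjamini–Yekutieli adjustment across terms within a cluster — BY
rather than BH because overlapping terms are arbitrarily dependent —
at a 0.05 cutoff. Generic list-overlap questions use the upper-tail
hypergeometric test.

## Paralog identification

Every protein is aligned locally (Smith–Waterman with affine gaps,
BLOSUM62, gap open 11 / extend 1) against every other. Scores become
E-values under the Karlin–Altschul model `E = K m n exp(-lambda S)`
with the standard published gapped constants `lambda = 0.267,
K = 0.041` for this scheme; `m` is the query length and `n` the total
residues searched. Hits must reach `E <= 1e-20` and cover at least
80 % of the query (the contiguous query span of the local alignment);
self-hits are removed, duplicate subjects collapse to their best hit,
and the 5 lowest-E hits are kept per query. The retained list is
directional — A may list B without B listing A — which is the per-query
reading of "top 5 non-reciprocal"; reciprocity is deliberately not
required, and the cut can be changed via `top_n`.

Two engineering choices matter here. First, each unordered pair is
aligned once: the raw local score is symmetric, and the one optimal
alignment yields the query span for both directions. Second, an exact
5-mer seeding prefilter (an inverted word index; candidate pairs must
share at least two distinct 5-mers) skips pairs that cannot plausibly
reach the E-value cutoff — a score clearing `E <= 1e-20` requires a
long stretch of near-identity, which shares many exact words. The
prefilter is configurable and `seed_k = 0` forces the exhaustive scan;
on test proteomes the two give identical results.

## The synthetic study

The generator emulates the design of the real experiment: 14
time-points spanning 13 days with 0.5–1-day intervals early and 2-day
intervals late (the default grid is
`0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 7, 9, 11, 13`; the exact
published sampling days are not fully enumerated anywhere, so the grid
is configurable rather than asserted), three replicate series, and a
common-reference M-value readout. Its components:

* **Archetypes.** Fifteen smooth unit-amplitude temporal shapes —
  early/mid/late activation and repression, transient bumps and dips
  at successive stages, a bimodal profile, and broad rise–fall shapes —
  mimicking the profile families of known floral regulators. A
  configurable fraction of genes (default 0.3) receives an archetype
  and a per-gene amplitude drawn uniformly in `[0.5, 1.5] * fc_scale`
  (default `fc_scale = 2`, i.e. typical 2-fold to 8-fold swings);
  the rest are flat. Residual variances come from a scaled
  inverse-chi-square prior (default `d0 = 4, s0_sq = 0.05`, giving
  replicate SDs around 0.2 on the log2 scale — realistic for good
  two-channel arrays). The truth table records, per gene, the
  archetype, variance, amplitude, and the largest true |log2 FC|
  reachable inside a 2-day contrast window, which is the effect size
  against which sensitivity is scored.
* **Raw arrays.** Probe-level red/green foreground and background
  intensities with per-gene baselines (log2 scale, mean 10, SD 1.5,
  truncated away from the control level so that only deliberately
  planted genes fall below background), additive background, optional
  intensity-dependent dye bias along a smooth exported basis, multiple
  probes per gene, and a block of labelled negative controls at an
  ambient level of about 2^6.
* **Annotations.** Bound-gene sets, paralog membership and term
  annotations are planted at exact counts so that the realized odds
  ratio of target clusters versus background matches the request up to
  rounding; an infeasible request errors with the layer's name. Bound
  genes additionally receive a peak placed inside their regulatory
  window on synthetic chromosomes whose genes are spaced 20 kb apart,
  so peak-to-gene assignment recovers the planted sets exactly.
  Paralog families are mutated copies of a common ancestral sequence;
  each member diverges at half the target divergence so that the
  configured `identity` is the expected *pairwise* identity within the
  family. The atlas boosts each planted gene's designated tissue above
  its other tissues.
* **Seeding.** One RNG stream per layer (expression, raw arrays,
  annotations, sequences) is derived from the master seed, so layers
  can be regenerated independently and every output is reproducible
  bit for bit.

What passing the synthetic validation shows: the statistics are
implemented correctly (exact agreement with oracles), error rates are
controlled under the generative model, and planted structure of
realistic magnitude is recovered end to end. What it does not show:
robustness to features real arrays have and the generator does not —
spatial artefacts, probe cross-hybridization, dye-swap designs,
outlier arrays, heavy-tailed noise, correlated genes within pathways,
or atlas batch effects. Results on real data should be judged with
those limitations in mind.

## Problem sizes and runtime choices

The test suite exercises the pipeline at deliberately compact sizes:
2,000-gene studies for error-rate checks (20 seeds), 900 genes for
cluster recovery, 100-protein proteomes for paralog properties, and
one study-proportioned end-to-end run with 10,000 genes and 15
clusters of roughly 200 genes — the scale at which all planted
enrichment layers (odds ratio 4) are decisively beyond the 3-SD rule.
Exhaustive oracle enumeration covers every 2x2 table up to N = 30 and
samples larger tables to N = 60; alignment oracles cover random pairs
up to 25 residues, where brute-force dynamic programming is exact and
fast. These sizes are the package's own validation design.

## Known limitations

* The pipeline models a one-way layout on time-point; it does not fit
  replicate or batch effects, and dye-swap designs are out of scope.
* The F-scan and windowed contrasts share the moderated variance; the
  two-stage DEG definition is a filtering scheme, not a joint model.
* Karlin–Altschul constants are scheme defaults, not estimated from
  the scoring matrix; absolute E-values inherit that approximation
  (the relative ordering of hits does not).
* The elbow suggestion is a heuristic on a heuristic; it is reported,
  never applied.
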