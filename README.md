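# floraltc

Time-course transcriptomics of *Arabidopsis* flower development.

`floraltc` re-implements, as a tested and reusable R pipeline, the
analysis of a dense floral time course measured on two-channel
common-reference microarrays: floral buds sampled at 14 time-points
over 13 days of synchronized flower development, in three biologically
independent replicate series, each array hybridized against a pooled
common reference so that every measurement is an M-value
(log2 of sample over reference). The package is aimed at analysts who
want to run the same statistical machinery on their own time-course
data, or to study its operating characteristics on fully synthetic
studies with known ground truth.

## What the pipeline computes

1. **Preprocessing** (`preprocess_raw`): background correction by the
   subtract method, within-array loess normalization of M on A,
   between-array A-quantile normalization, probe-to-gene averaging,
   and removal of genes below the median intensity of negative-control
   probes.
2. **Differential expression** (`fit_timecourse`,
   `moderate_variances`, `global_f_test`, `windowed_contrasts`,
   `call_degs`): per-gene one-way linear models over the time grid;
   empirical-Bayes moderation of the residual variances, shrinking
   each gene's s² toward a prior scale s₀² with prior degrees of
   freedom d₀ estimated by moment matching,

       s̃²_g = (d₀ s₀² + d_g s²_g) / (d₀ + d_g);

   a moderated F-scan for any change over the course; then all
   contrasts between time-points within a 2-day window, tested with
   moderated t-statistics and one Benjamini–Hochberg adjustment pooled
   across the whole experiment. A gene is differentially expressed if
   some windowed contrast has adjusted p < 0.01 and fold change ≥ 1.7.
3. **Co-expression clustering** (`zscore_profiles`, `kmeans_cluster`,
   `elbow_curve`): k-means (default k = 15) on z-scored
   replicate-averaged profiles, with a BSS/TSS elbow curve to guide
   the choice of k.
4. **Tissue-atlas mapping** (`map_extreme_tissue`): per cluster, the
   percentage of genes whose atlas expression maximum (and minimum)
   falls in each tissue group.
5. **Gene-set enrichment by resampling**
   (`resampling_set_enrichment`): a cluster's annotated fraction is
   compared with 100 equally sized random gene sets drawn from a
   background universe (the DEG list and/or all genes on the array);
   clusters beyond 3 standard deviations of the resampled null are
   flagged. `assign_peaks_to_genes` builds bound-gene sets from
   binding peaks with a strand-aware −3 kb/+1 kb window around the
   transcribed region.
6. **Term enrichment** (`go_enrichment`): one-sided Fisher exact tests
   with Benjamini–Yekutieli correction at a 0.05 cutoff;
   `list_overlap_test` gives hypergeometric overlap tests between gene
   lists.
7. **Paralog identification** (`find_paralogs`): all-vs-all local
   protein alignment (BLOSUM62, affine gaps), Karlin–Altschul
   E-values, filters E ≤ 1e-20 and query coverage ≥ 80 %, top-5 hits
   per query.

A synthetic-data generator (`sim_config`, `generate_timecourse`,
`generate_raw_two_channel`, `generate_annotations`) emulates the whole
study — temporal expression archetypes, raw two-channel intensities
with dye bias and negative controls, a tissue atlas, binding peaks
with gene models, term annotations, and a proteome with mutated
paralog families — together with a ground-truth table, so the full
pipeline can be exercised and validated without any external data.
`run_pipeline` orchestrates everything from a single `run_config`.

## Worked example

```r
library(floraltc)

cfg  <- sim_config(n_genes = 2000, frac_de = 0.3, seed = 42)
sim  <- generate_timecourse(cfg)
sim$expr
#> ExpressionMatrix: 2000 genes x 42 arrays
#>   time-points (d): 0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 7, 9, 11, 13
#>   replicates: 3  (no A-values)

mfit <- moderate_variances(fit_timecourse(sim$expr))
mfit
#> ModeratedFit: 2000 genes, prior d0 = 3.93, s0^2 = 0.04812

degs <- call_degs(windowed_contrasts(mfit, window_days = 2),
                  alpha = 0.01, fc_min = 1.7)
degs
#> DEGTable: 602 of 2000 genes called DE (alpha = 0.01, FC >= 1.7)

z  <- zscore_profiles(sim$expr, degs$gene[degs$deg])
cl <- kmeans_cluster(z, k = 15, seed = 42)
cl
#> ClusterAssignment: 602 genes in 15 clusters (BSS/TSS = 0.946)

ann   <- generate_annotations(cfg, sim$truth)
bound <- assign_peaks_to_genes(ann$peaks$TF1, ann$gene_models)
er    <- resampling_set_enrichment(cl, bound, degs$gene[degs$deg],
                                   n_iter = 100, seed = 42,
                                   background_label = "DEGs")
head(as.data.frame(er)[order(-er$z), ], 4)
#>    cluster  n p_obs null_mean null_sd     z significant
#> 12      12 38 0.395     0.140  0.0572 4.447        TRUE
#> 7        7 40 0.275     0.136  0.0509 2.725       FALSE
#> 13      13 38 0.263     0.139  0.0639 1.943       FALSE
#> 5        5 40 0.150     0.141  0.0451 0.194       FALSE
```

Reading the output: the moderated fit recovers the variance prior the
data were generated from (d₀ = 4, s₀² = 0.05); 602 of 2000 genes pass
the windowed-contrast thresholds (600 were planted); the clusters
explain 94.6 % of the profile variance; and one cluster carries 39.5 %
bound genes against a resampled null of 14.0 ± 5.7 %, i.e. 4.4
standard deviations above it, and is flagged as enriched for binding.

## Vignette

`vignettes/floraltc-methods.Rmd` documents the statistical model, the
synthetic-data design, every tunable threshold with its default, and
the package's design decisions and limitations.
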