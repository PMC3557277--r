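# slrpipe

Replicate-consistency filtering and consensus clustering of microarray
expression time courses, built for the DMM mouse model of osteoarthritis
(destabilization of the medial meniscus) and its sham-operated controls —
and for any replicated design of the same shape: pooled biological
replicates measured at a few timepoints against averaged baseline
controls, with a dual-layer expression matrix carrying log2 signal
intensity and a detection p-value per probe set and array.

## What it computes

**Signal log ratios.** Differential expression is the signal log ratio
`SLR = log2(sample) − log2(control average)`; an SLR of 0.5 is a 1.4-fold
change. Sham pools are compared against the averaged time-0 baseline;
DMM pools against the averaged time-matched sham. Each replicate is kept
separate (12 sham / 11 DMM SLR values per probe under the study design
with one missing 2-week DMM pool), with an explicit availability mask for
missing arrays.

**A four-stage filter** defines "consistently and significantly
differentially expressed": per replicate, detection p ≤ 0.06 in every
contributing array and |SLR| ≥ 0.5 at ≥ 1 timepoint; then the
intersection across replicates; then an all-by-all replicate comparison
in which at least 2 of the 3 pairwise Pearson correlations must be
≥ 0.70 and at least 2 of the 3 pairwise Euclidean distances must be at
or below a cutoff (explicit, or derived as the median of the entering
ED scores). All bounds are inclusive; the cascade is monotone and every
intermediate count is reported.

**Cluster-number selection and consensus clustering.** A
leave-one-timepoint-out figure of merit (root-mean-square deviation of
held-out values from cluster means, adjusted by `sqrt(n/(n−k))`,
best-of-10 k-means starts per fit) locates the number of clusters at the
curve's elbow. Consensus clustering then runs seeded k-means 10 times
per replicate dataset, thresholds the co-clustering fraction matrix at
0.83, and reports the connected components (depth-first search) of size
≥ 2 as consensus clusters and size-1 components as singletons.

**A synthetic-data generator** reproduces the study design (3 baseline
pools, sham/DMM × 4 timepoints × 3 pools, one missing 2-week DMM pool)
with planted phasic expression templates and truth labels, so filter
sensitivity/specificity and cluster recovery are benchmarked end to end
without any array download.

## Worked example

```r
library(slrpipe)

ds  <- generate_dataset(synthetic_spec(seed = 7))   # 1000 probes, 100 planted DE
res <- run_filter_pipeline(ds$matrix, "dmm_vs_sham", filter_params(ed_max = 0.60))
res$report
#> filter cascade (dmm_vs_sham)
#>   detection p <= 0.06, |SLR| >= 0.5, PCC >= 0.7, ED <= 0.6 (explicit), 2 of 3 pairs
#>           step replicate n_probes n_genes
#>          input       all     1000      NA
#>      detection      rep1      910      NA
#>            slr      rep1      105      NA
#>  detection+slr      rep1      104      NA
#>      detection      rep2      910      NA
#>            slr      rep2      109      NA
#>  detection+slr      rep2      106      NA
#>      detection      rep3      910      NA
#>            slr      rep3      105      NA
#>  detection+slr      rep3      104      NA
#>        overlap       all       90      NA
#>    consistency       all       89      NA

keep     <- res$probes
datasets <- lapply(1:3, function(r) replicate_profiles(res$tcs, r, keep))
fom <- fom_analysis(datasets[[3]], 2:10, seed = 7)
fom_pick_k(fom)
#> [1] 5

cc <- consensus_cluster(datasets, consensus_params(k = 5, seed = 7))
cc
#> consensus_result: 5 clusters (size >= 2), 0 singletons, 30 runs, threshold 0.83
#> cluster sizes: 19, 19, 18, 17, 16

planted_recovery_report(res$probes, ds$truth, consensus = cc)
#> sensitivity 0.989  specificity 1.000  ARI 1.000
```

Reading the output: of 1000 probes, 910 are detected above background;
the SLR filter leaves ~105 per replicate; 90 pass in all three
replicates and 89 are replicate-consistent — 89 of the 100 planted DE
probes (the 10 planted as replicate-inconsistent are removed at the
overlap step, as intended, and one consistent probe is lost to noise).
The FOM elbow finds the five planted temporal templates, and consensus
clustering recovers them exactly (adjusted Rand index 1.0).

The same run, with TSV outputs and a reproducible manifest:

```r
run_pipeline(run_config(out_dir = "run1",
                        synthetic = synthetic_spec(seed = 7),
                        filter = filter_params(ed_max = 0.60),
                        consensus = consensus_params(k = 5),
                        select_k_by_fom = TRUE, seed = 7))
```

See `vignettes/timecourse-filtering.Rmd` for the model, the parameter
conventions (including when the median ED cutoff is and is not
meaningful), and the generator's assumptions.

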