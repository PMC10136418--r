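# tinnbench

Semi-supervised benchmarking of clustering pipelines for tinnitus
subphenotyping — or for any mixed-type patient cohort that carries a
*partial* expert labeling.

## The problem

Tinnitus patients are heterogeneous, but a minority can be assigned to a
diagnosed endotype (pulsatile tinnitus, otosclerosis, Menière's disease,
vestibular schwannoma, ...). A purely unsupervised clustering of
questionnaire data has no yardstick; the partial diagnoses provide one. A
candidate clustering is worth attention when it (a) isolates the known
endotypes into homogeneous clusters, and (b) is stable under resampling.
`tinnbench` turns this into a quantitative benchmark over combinations of
dimensionality reductions (PCA, factor analysis of mixed data, t-SNE) and
clusterers (k-means, DBSCAN).

The three scores, per hyperparameter grid point and averaged over three
endotype-stratified 50-50 partitionings of the cohort:

* **V-measure** at β = 0.1 against the labeled subset,
  `V = (1+β)hc / (βh + c)` with homogeneity `h = 1 − H(C|K)/H(C)` and
  completeness `c = 1 − H(K|C)/H(K)` — the primary criterion;
* **stability**: for k-means, fit both halves, cross-predict, and average
  the two same-half adjusted mutual informations
  `AMI = (MI − E{MI}) / (max{H(U),H(V)} − E{MI})` with the expectation
  computed exactly under the fixed-marginals permutation null; for DBSCAN
  (transductive), the train/test cluster-count difference;
* **silhouette** in the reduced space, reported but not decisive.

Solutions with averaged AMI ≥ 0.7 (k-means) or count difference 0 (DBSCAN)
are eligible; the best-V eligible records are shortlisted and
characterized by pooled Cohen's D cluster profiles and observed-vs-random
endotype repartition tables.

Because clinical databases of this kind are private, the package ships a
synthetic cohort generator (`tinnitus_cohort_spec()`) emulating a
2772-patient case-history table: 42 mixed features with published-scale
moments, six endotypes at realistic prevalences (12.59% labeled overall),
planted effect-size signatures, and injectable missingness — so the whole
pipeline is exercisable and testable end to end.

## Worked example

```r
library(tinnbench)

spec   <- tinnitus_cohort_spec(n_patients = 2000)
cohort <- generate_cohort(spec, seed = 1)
splits <- stratified_splits(cohort$labels, n_partitionings = 3, seed = 2)

grid <- grid_spec(tsne_components = 2, tsne_perplexity = c(30, 75),
                  kmeans_k = c(6, 8, 10))
records <- run_benchmark(cohort$table, splits, grid, seed = 3,
                         reductions = "tsne", clusterers = "kmeans")
best_performance_table(records)
#>   reduction clusterer v_measure stability silhouette
#> 1      tsne    kmeans 0.7404833 0.6676266  0.3480402

top <- shortlist(filter_eligible(records), splits, n = 1)[[1]]
top$record
#> benchmark_record: tsne + kmeans | V = 0.7140, stability = 0.7044, silhouette = 0.3383
```

The best *eligible* grid point (stability ≥ 0.7) reaches a V-measure of
0.71: its clusters are nearly homogeneous in the planted endotypes. Its
representative clustering (the training half of the partitioning with the
best per-partitioning V) can be profiled:

```r
prof <- profile_clusters(cohort$table[top$indices, ], top$assignment)
head(subset(prof, cluster == 3), 4)
#>    cluster size       feature         d direction
#> 32       3  109 pulsatile=yes  2.159582  positive
#> 33       3  109  pulsatile=no -2.159582  negative
#> 34       3  109           age -1.383538  negative
#> 35       3  109 sleep_latency  1.299196  positive

rep_tab <- endotype_repartition(top$assignment, cohort$table$labels[top$indices])
subset(rep_tab, endotype == "pulsatile tinnitus" & observed > 0)
#>    cluster           endotype observed expected
#> 51       0 pulsatile tinnitus        1      8.4
#> 54       3 pulsatile tinnitus       77      8.4
#> 58       7 pulsatile tinnitus        2      8.4
```

Cluster 3 is a pulsatile-tinnitus cluster: 109 patients, dominated by the
pulsatile indicator (pooled Cohen's D = 2.16), younger than the rest of the
cohort, and holding 77 of the half-cohort's 84 labeled pulsatile patients
where a random allocation over the 10 clusters would place 8.4 there.

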