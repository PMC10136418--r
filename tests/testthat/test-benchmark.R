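# minimal hand-built record for filter/shortlist unit tests
fake_record <- function(method = "kmeans", v = 0.3, stab = 0.8, sil = 0.2,
                        stab_per_part = rep(stab, 3), k = 5) {
  structure(list(
    reduction = list(method = "pca", n_components = 2),
    clusterer = if (method == "kmeans") list(method = "kmeans", k = k)
                else list(method = "dbscan", eps = 1, min_samples = 5),
    per_partitioning = data.frame(
      partitioning = 1:3, v_measure = v + c(-0.01, 0, 0.01),
      stability = stab_per_part, silhouette = rep(sil, 3),
      n_clusters_train = rep(k, 3), n_clusters_test = rep(k, 3)),
    v_measure_avg = v, stability_avg = mean(stab_per_part),
    silhouette_avg = sil,
    train_assignments = rep(list(cluster_assignment(rep(0:1, 5))), 3)),
    class = "benchmark_record")
}
as_records <- function(...) structure(list(...), class = "benchmark_records")

test_that("grid enumeration cardinality matches the closed-form product", {
  g <- grid_spec()
  n_red <- 19 + 19 + 5 * length(c(seq(5, 40, 5), seq(50, 200, 25)))
  n_clu <- 19 + 100 * 14
  expect_identical(grid_size(g), as.integer(n_red * n_clu))
  expect_identical(length(c(seq(5, 40, 5), seq(50, 200, 25))), 15L)
  # reduced grids multiply out too
  g2 <- grid_spec(tsne_components = 2, tsne_perplexity = c(20, 30),
                  kmeans_k = c(3, 4, 5))
  expect_identical(grid_size(g2, reductions = "tsne", clusterers = "kmeans"),
                   2L * 3L)
})

test_that("a reduced sweep produces one record per grid point with exact averages", {
  spec <- tinnitus_cohort_spec(n_patients = 600)
  co <- generate_cohort(spec, seed = 31)
  splits <- stratified_splits(co$labels, 3, seed = 32)
  grid <- grid_spec(tsne_components = 2, tsne_perplexity = c(20, 30),
                    kmeans_k = c(3, 5, 7))
  recs <- run_benchmark(co$table, splits, grid, seed = 33,
                        reductions = "tsne", clusterers = "kmeans")
  expect_length(recs, 6)  # 2 perplexities x 3 k
  for (r in recs) {
    expect_equal(r$v_measure_avg, mean(r$per_partitioning$v_measure))
    expect_equal(r$stability_avg, mean(r$per_partitioning$stability))
    expect_equal(r$silhouette_avg, mean(r$per_partitioning$silhouette))
    expect_identical(nrow(r$per_partitioning), 3L)
  }
  df <- as.data.frame(recs)
  expect_identical(nrow(df), 6L)
  expect_setequal(df$k, c(3L, 5L, 7L))
})

test_that("all six method combinations appear in the benchmark report", {
  spec <- tinnitus_cohort_spec(n_patients = 400)
  co <- generate_cohort(spec, seed = 41)
  splits <- suppressWarnings(stratified_splits(co$labels, 3, seed = 42))
  grid <- grid_spec(pca_components = 2, famd_components = 2,
                    tsne_components = 2, tsne_perplexity = 20,
                    kmeans_k = 4,
                    dbscan_eps = c(0.2, 0.35, 0.4, 0.45, 0.75, 1, 1.5),
                    dbscan_min_samples = 4)
  recs <- run_benchmark(co$table, splits, grid, seed = 43)
  tab <- best_performance_table(recs)
  expect_identical(nrow(tab), 6L)
  expect_setequal(paste(tab$reduction, tab$clusterer),
                  c("pca kmeans", "pca dbscan", "famd kmeans",
                    "famd dbscan", "tsne kmeans", "tsne dbscan"))
  expect_identical(colnames(tab),
                   c("reduction", "clusterer", "v_measure", "stability",
                     "silhouette"))
})

test_that("the eligibility filter applies the AMI and count-difference thresholds", {
  recs <- as_records(
    fake_record("kmeans", stab_per_part = rep(0.69, 3)),
    fake_record("kmeans", stab_per_part = rep(0.71, 3)),
    fake_record("kmeans", stab_per_part = rep(0.70, 3)),
    fake_record("dbscan", stab_per_part = c(0, 0, 0)),
    fake_record("dbscan", stab_per_part = c(0, 1, 0)))
  kept <- filter_eligible(recs)
  expect_length(kept, 3)
  stabs <- vapply(kept, `[[`, numeric(1), "stability_avg")
  expect_true(all(stabs[1:2] >= 0.7))  # 0.69 excluded, 0.70 kept ("at least")
  expect_length(filter_eligible(as_records()), 0)  # empty in, empty out
})

test_that("shortlisting orders by V-measure with the stated tie-breaks", {
  labels <- sample(c("a", NO_DIAGNOSIS), 20, TRUE)
  sp <- stratified_splits(labels, 3, seed = 5)
  recs <- as_records(
    fake_record(v = 0.38, stab = 0.75, k = 5),
    fake_record(v = 0.35, stab = 0.9, k = 6),
    fake_record(v = 0.14, stab = 0.8, k = 7),
    fake_record(v = 0.10, stab = 0.8, k = 8))
  sl <- shortlist(recs, sp, n = 3)
  expect_length(sl, 3)
  expect_equal(vapply(sl, function(s) s$record$v_measure_avg, 0),
               c(0.38, 0.35, 0.14))
  # representative clustering: the partitioning with the best per-part V
  expect_identical(sl[[1]]$partitioning,
                   which.max(sl[[1]]$record$per_partitioning$v_measure))
  expect_identical(sl[[1]]$indices, sp$partitionings[[3]]$train)
  # tie on V: higher stability wins
  tied <- as_records(fake_record(v = 0.3, stab = 0.72, k = 5),
                     fake_record(v = 0.3, stab = 0.95, k = 6))
  sl2 <- shortlist(tied, sp, n = 1)
  expect_equal(sl2[[1]]$record$stability_avg, 0.95)
  expect_warning(shortlist(tied, sp, n = 3), "eligible")
})

test_that("cluster profiles report pooled Cohen's D with the stated conventions", {
  set.seed(51)
  n <- 200
  cl <- rep(c(0L, 1L), each = n / 2)
  d <- data.frame(
    up = c(rnorm(n / 2, 10, 2), rnorm(n / 2, 8, 2)),   # D about +1
    flat = rnorm(n),                                    # equal means: absent
    marker = factor(ifelse(cl == 0, "yes", "no")))      # perfect separator
  tab <- patient_table(d)
  prof <- profile_clusters(tab, cluster_assignment(cl), d_threshold = 0.3)
  c0 <- prof[prof$cluster == 0, ]
  expect_false("flat" %in% prof$feature)
  d_up <- c0$d[c0$feature == "up"]
  x <- d$up
  sp_ <- sqrt(((n / 2 - 1) * var(x[cl == 0]) + (n / 2 - 1) * var(x[cl == 1])) /
                (n - 2))
  expect_equal(d_up, (mean(x[cl == 0]) - mean(x[cl == 1])) / sp_,
               tolerance = 1e-12)
  expect_identical(c0$direction[c0$feature == "up"], "positive")
  # perfectly separating indicator: infinite D rendered as ">10"
  expect_true(is.infinite(c0$d[c0$feature == "marker=yes"]))
  expect_identical(format_effect_size(c0$d[c0$feature == "marker=yes"]),
                   ">10")
  # sorted by |D| within cluster (infinite entries lead)
  fin <- is.finite(c0$d)
  expect_true(all(!fin[1:sum(!fin)]))  # infinities first
  expect_true(all(diff(abs(c0$d[fin])) <= 0))
})

test_that("endotype repartition uses the uniform-over-clusters null", {
  # 116 labeled patients of one endotype spread over 20 clusters
  set.seed(52)
  lab_cluster <- sample(0:19, 300, TRUE)
  labels <- c(rep("pulsatile", 116), rep(NO_DIAGNOSIS, 184))
  rep_ <- endotype_repartition(cluster_assignment(lab_cluster), labels)
  expect_equal(unique(rep_$expected), 116 / 20)  # 5.8
  expect_identical(sum(rep_$observed), 116L)
  # absent endotype: all-zero rows when explicitly requested
  rep2 <- endotype_repartition(cluster_assignment(lab_cluster), labels,
                               endotypes = c("pulsatile", "otosclerosis"))
  oto <- rep2[rep2$endotype == "otosclerosis", ]
  expect_true(all(oto$observed == 0) && all(oto$expected == 0))
})
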