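#' Hyperparameter grid for the clustering benchmark
#'
#' Defaults reproduce the full published search space: 2-20 components for
#' PCA and FAMD, 2-6 components and perplexity \{5, 10, ..., 40\} union
#' \{50, 75, ..., 200\} for t-SNE, k = 2-20 for k-means, eps = 0.1-10 by
#' 0.1 and min_samples = 2-15 for DBSCAN, with DBSCAN solutions accepted
#' only when both halves produce between `dbscan_cluster_range[1]` and
#' `dbscan_cluster_range[2]` clusters.
#'
#' @param pca_components,famd_components,tsne_components integer vectors
#' @param tsne_perplexity numeric vector of perplexities
#' @param kmeans_k integer vector of cluster counts
#' @param dbscan_eps numeric vector of radii (> 0)
#' @param dbscan_min_samples integer vector
#' @param dbscan_cluster_range length-2 accepted cluster-count range
#' @return a `grid_spec`
#' @export
grid_spec <- function(pca_components = 2:20,
                      famd_components = 2:20,
                      tsne_components = 2:6,
                      tsne_perplexity = c(seq(5, 40, by = 5),
                                          seq(50, 200, by = 25)),
                      kmeans_k = 2:20,
                      dbscan_eps = seq(0.1, 10, by = 0.1),
                      dbscan_min_samples = 2:15,
                      dbscan_cluster_range = c(2, 20)) {
  stopifnot(length(pca_components) > 0, length(famd_components) > 0,
            length(tsne_components) > 0, length(tsne_perplexity) > 0,
            length(kmeans_k) > 0, length(dbscan_eps) > 0,
            length(dbscan_min_samples) > 0,
            all(dbscan_eps > 0), length(dbscan_cluster_range) == 2)
  structure(list(pca_components = as.integer(pca_components),
                 famd_components = as.integer(famd_components),
                 tsne_components = as.integer(tsne_components),
                 tsne_perplexity = as.numeric(tsne_perplexity),
                 kmeans_k = as.integer(kmeans_k),
                 dbscan_eps = as.numeric(dbscan_eps),
                 dbscan_min_samples = as.integer(dbscan_min_samples),
                 dbscan_cluster_range = as.integer(dbscan_cluster_range)),
            class = "grid_spec")
}

reduction_configs <- function(grid, methods) {
  cfgs <- list()
  if ("pca" %in% methods)
    for (d in grid$pca_components)
      cfgs[[length(cfgs) + 1]] <- list(method = "pca", n_components = d)
  if ("famd" %in% methods)
    for (d in grid$famd_components)
      cfgs[[length(cfgs) + 1]] <- list(method = "famd", n_components = d)
  if ("tsne" %in% methods)
    for (d in grid$tsne_components)
      for (px in grid$tsne_perplexity)
        cfgs[[length(cfgs) + 1]] <- list(method = "tsne", n_components = d,
                                         perplexity = px)
  cfgs
}

clusterer_configs <- function(grid, methods) {
  cfgs <- list()
  if ("kmeans" %in% methods)
    for (k in grid$kmeans_k)
      cfgs[[length(cfgs) + 1]] <- list(method = "kmeans", k = k)
  if ("dbscan" %in% methods)
    for (eps in grid$dbscan_eps)
      for (ms in grid$dbscan_min_samples)
        cfgs[[length(cfgs) + 1]] <- list(method = "dbscan", eps = eps,
                                         min_samples = ms)
  cfgs
}

#' Number of grid points a benchmark sweep enumerates
#'
#' @param grid a [grid_spec()]
#' @param reductions,clusterers method subsets
#' @return integer count: (number of reduction configurations) x (number
#'   of clusterer configurations)
#' @export
grid_size <- function(grid, reductions = c("pca", "famd", "tsne"),
                      clusterers = c("kmeans", "dbscan")) {
  length(reduction_configs(grid, reductions)) *
    length(clusterer_configs(grid, clusterers))
}

reduce_half <- function(table, idx, cfg, seed) {
  half <- table[idx, ]
  switch(cfg$method,
    pca = reduce_pca(encode(half), cfg$n_components),
    famd = reduce_famd(half, cfg$n_components),
    tsne = reduce_tsne(encode(half), cfg$n_components,
                       perplexity = cfg$perplexity, seed = seed),
    stop("unknown reduction method: ", cfg$method))
}

#' Run the semi-supervised clustering benchmark
#'
#' For every (dimensionality reduction configuration x clusterer
#' configuration) pair of the grid and each of the partitionings: both
#' halves are reduced independently with identical hyperparameters and
#' seed; k-means is fit on the training half and scored with the
#' four-clustering AMI stability protocol, while DBSCAN is fit on each
#' half and scored by the cluster-count difference; the V-measure (against
#' the table's partial labels, training-half fit) and the silhouette (in
#' the reduced space) complete the record. Per-partitioning values and
#' their means are stored. DBSCAN solutions whose cluster count leaves
#' `grid$dbscan_cluster_range` on either half of any partitioning are
#' discarded, and grid points that fail (e.g. all-noise DBSCAN) are
#' recorded as errors, not fatal.
#'
#' @param table a preprocessed (fully imputed) [patient_table()]
#' @param splits a `split_set` from [stratified_splits()]
#' @param grid a [grid_spec()]
#' @param seed integer seed used for reductions and clustering fits
#' @param reductions subset of `c("pca", "famd", "tsne")`
#' @param clusterers subset of `c("kmeans", "dbscan")`
#' @param beta V-measure beta (default 0.1)
#' @param n_init k-means restarts
#' @param verbose print progress per reduction configuration
#' @return a `benchmark_records` list; see [as.data.frame.benchmark_records()]
#' @export
run_benchmark <- function(table, splits, grid = grid_spec(), seed = 1L,
                          reductions = c("pca", "famd", "tsne"),
                          clusterers = c("kmeans", "dbscan"),
                          beta = 0.1, n_init = 10, verbose = FALSE) {
  stopifnot(inherits(table, "patient_table"), inherits(splits, "split_set"))
  if (any(missing_mask(table)))
    stop("table still contains missing cells; run the preprocessing first")
  red_cfgs <- reduction_configs(grid, reductions)
  clu_cfgs <- clusterer_configs(grid, clusterers)
  n_parts <- length(splits$partitionings)
  records <- list()
  failures <- list()

  for (rc in red_cfgs) {
    if (verbose)
      message("reduction: ", rc$method, " ",
              paste(names(rc)[-1], unlist(rc[-1]), sep = "=", collapse = " "))
    embs <- vector("list", n_parts)
    red_err <- NULL
    for (p in seq_len(n_parts)) {
      part <- splits$partitionings[[p]]
      embs[[p]] <- tryCatch(
        list(train = reduce_half(table, part$train, rc, seed),
             test = reduce_half(table, part$test, rc, seed)),
        error = function(e) e)
      if (inherits(embs[[p]], "error")) { red_err <- embs[[p]]; break }
    }
    if (!is.null(red_err)) {
      failures[[length(failures) + 1]] <-
        list(reduction = rc, error = conditionMessage(red_err))
      next
    }

    for (cc in clu_cfgs) {
      rec <- tryCatch(
        score_grid_point(table, splits, embs, rc, cc, grid, seed,
                         beta = beta, n_init = n_init),
        error = function(e) e)
      if (inherits(rec, "error")) {
        failures[[length(failures) + 1]] <-
          list(reduction = rc, clusterer = cc,
               error = conditionMessage(rec))
      } else if (!is.null(rec)) {
        records[[length(records) + 1]] <- rec
      }
    }
  }
  structure(records, class = "benchmark_records", failures = failures,
            beta = beta)
}

score_grid_point <- function(table, splits, embs, rc, cc, grid, seed,
                             beta, n_init) {
  n_parts <- length(splits$partitionings)
  v <- numeric(n_parts); stab <- numeric(n_parts); sil <- numeric(n_parts)
  ncl_tr <- integer(n_parts); ncl_te <- integer(n_parts)
  assigns <- vector("list", n_parts)

  for (p in seq_len(n_parts)) {
    part <- splits$partitionings[[p]]
    tr_emb <- embs[[p]]$train; te_emb <- embs[[p]]$test
    if (cc$method == "kmeans") {
      st <- stability_inductive(tr_emb, te_emb, cc$k, seed = seed,
                                n_init = n_init)
      tr_assign <- st$fit_train$assignment
      stab[p] <- st$value
      ncl_tr[p] <- cc$k; ncl_te[p] <- cc$k
    } else {
      tr_assign <- fit_dbscan(tr_emb, cc$eps, cc$min_samples)
      te_assign <- fit_dbscan(te_emb, cc$eps, cc$min_samples)
      rng <- grid$dbscan_cluster_range
      if (tr_assign$n_clusters < rng[1] || tr_assign$n_clusters > rng[2] ||
          te_assign$n_clusters < rng[1] || te_assign$n_clusters > rng[2])
        return(NULL)  # outside the accepted cluster-count range: discard
      stab[p] <- stability_transductive(tr_assign, te_assign)$value
      ncl_tr[p] <- tr_assign$n_clusters; ncl_te[p] <- te_assign$n_clusters
    }
    v[p] <- v_measure(table$labels[part$train], tr_assign, beta = beta)$v
    sil[p] <- silhouette_mean(tr_emb, tr_assign)
    assigns[[p]] <- tr_assign
  }

  structure(list(
    reduction = rc, clusterer = cc,
    per_partitioning = data.frame(
      partitioning = seq_len(n_parts), v_measure = v, stability = stab,
      silhouette = sil, n_clusters_train = ncl_tr, n_clusters_test = ncl_te),
    v_measure_avg = mean(v), stability_avg = mean(stab),
    silhouette_avg = mean(sil),
    train_assignments = assigns),
    class = "benchmark_record")
}

#' @export
print.benchmark_record <- function(x, ...) {
  cat(sprintf("benchmark_record: %s + %s | V = %.4f, stability = %.4f, silhouette = %.4f\n",
              x$reduction$method, x$clusterer$method,
              x$v_measure_avg, x$stability_avg, x$silhouette_avg))
  invisible(x)
}

#' Flatten benchmark records to a data frame
#'
#' @param x a `benchmark_records` list from [run_benchmark()]
#' @param ... ignored
#' @return data.frame with one row per grid point: methods,
#'   hyperparameters, averaged metrics
#' @export
as.data.frame.benchmark_records <- function(x, ...) {
  if (!length(x)) return(data.frame())
  do.call(rbind, lapply(x, function(r) {
    data.frame(
      reduction = r$reduction$method,
      n_components = r$reduction$n_components,
      perplexity = if (is.null(r$reduction$perplexity)) NA_real_
                   else r$reduction$perplexity,
      clusterer = r$clusterer$method,
      k = if (is.null(r$clusterer$k)) NA_integer_ else r$clusterer$k,
      eps = if (is.null(r$clusterer$eps)) NA_real_ else r$clusterer$eps,
      min_samples = if (is.null(r$clusterer$min_samples)) NA_integer_
                    else r$clusterer$min_samples,
      v_measure = r$v_measure_avg,
      stability = r$stability_avg,
      silhouette = r$silhouette_avg,
      stringsAsFactors = FALSE)
  }))
}

#' Keep only grid points passing the stability eligibility filter
#'
#' k-means records are eligible when their averaged four-clustering AMI is
#' at least `ami_min`; DBSCAN records when the cluster-count difference is
#' at most `max_count_diff` on every partitioning.
#'
#' @param records a `benchmark_records` list
#' @param ami_min AMI eligibility threshold (default 0.7)
#' @param max_count_diff tolerated DBSCAN count difference (default 0)
#' @return the eligible subset, same class (possibly empty)
#' @export
filter_eligible <- function(records, ami_min = 0.7, max_count_diff = 0) {
  keep <- vapply(records, function(r) {
    if (r$clusterer$method == "kmeans") r$stability_avg >= ami_min
    else all(r$per_partitioning$stability <= max_count_diff)
  }, logical(1))
  structure(records[keep], class = "benchmark_records",
            failures = attr(records, "failures"), beta = attr(records, "beta"))
}

#' Shortlist the best benchmark records
#'
#' Orders eligible records by averaged V-measure (descending), breaking
#' ties by stability (higher AMI / lower count difference), then
#' silhouette, then the smaller hyperparameter tuple, and returns the top
#' `n` together with each record's representative clustering: the
#' training-half clustering of the partitioning achieving the record's
#' best per-partitioning V-measure.
#'
#' @param records a `benchmark_records` list (after [filter_eligible()])
#' @param splits the `split_set` the records were benchmarked on
#' @param n shortlist size (default 3); if fewer records are eligible, all
#'   are returned with a warning
#' @return list of entries: `record`, `partitioning` (index),
#'   `assignment` (the representative [cluster_assignment()]), `indices`
#'   (training-half patient indices)
#' @export
shortlist <- function(records, splits, n = 3) {
  if (!length(records)) return(list())
  stab_key <- vapply(records, function(r)
    if (r$clusterer$method == "kmeans") r$stability_avg
    else -r$stability_avg, numeric(1))
  v <- vapply(records, `[[`, numeric(1), "v_measure_avg")
  sil <- vapply(records, `[[`, numeric(1), "silhouette_avg")
  hp <- vapply(records, function(r)
    paste(r$reduction$method, r$clusterer$method,
          paste(sprintf("%012.4f",
                        as.numeric(unlist(c(r$reduction[-1],
                                            r$clusterer[-1])))),
                collapse = ","), sep = "|"), character(1))
  ord <- order(-v, -stab_key, -sil, hp)
  if (length(records) < n)
    warning("only ", length(records), " eligible record(s); returning all")
  top <- ord[seq_len(min(n, length(records)))]
  lapply(top, function(i) {
    r <- records[[i]]
    best_p <- which.max(r$per_partitioning$v_measure)
    list(record = r, partitioning = best_p,
         assignment = r$train_assignments[[best_p]],
         indices = splits$partitionings[[best_p]]$train)
  })
}

#' Best-performance comparison table
#'
#' One row per (reduction method x clusterer method) combination with the
#' metrics of its best grid point by averaged V-measure - the benchmark's
#' final report shape.
#'
#' @param records a `benchmark_records` list
#' @return data.frame: reduction, clusterer, v_measure, stability,
#'   silhouette
#' @export
best_performance_table <- function(records) {
  df <- as.data.frame(records)
  if (!nrow(df)) return(df)
  combos <- unique(df[, c("reduction", "clusterer")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- df[df$reduction == combos$reduction[i] &
                df$clusterer == combos$clusterer[i], ]
    sub[which.max(sub$v_measure),
        c("reduction", "clusterer", "v_measure", "stability", "silhouette")]
  }))
  rownames(out) <- NULL
  out
}
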