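as_label_vector <- function(x) {
  if (inherits(x, "cluster_assignment")) x$labels else x
}

#' Shannon entropy of a partition
#'
#' Entropy of the cluster-size proportions in natural log units (nats).
#' All derived scores (AMI, V-measure) are ratios and therefore invariant
#' to the log base.
#'
#' @param partition a [cluster_assignment()] or a plain label vector
#' @return entropy in nats
#' @export
partition_entropy <- function(partition) {
  labels <- as_label_vector(partition)
  stopifnot(length(labels) >= 1)
  p <- table(labels) / length(labels)
  p <- as.numeric(p[p > 0])
  -sum(p * log(p))
}

#' Contingency table of two partitions
#'
#' Cross-tabulation of co-occurrence counts between two labelings of the
#' same samples; the carrier of every entropy / mutual-information quantity
#' used by the AMI and the V-measure.
#'
#' @param u,v label vectors or [cluster_assignment()]s over the same samples
#' @return a `contingency_table`: list with `counts` (|U| x |V| matrix) and
#'   `n`
#' @export
contingency_table <- function(u, v) {
  u <- as_label_vector(u); v <- as_label_vector(v)
  stopifnot(length(u) == length(v), length(u) >= 1)
  counts <- table(u, v)
  structure(list(counts = unclass(counts), n = length(u)),
            class = "contingency_table")
}

# Mutual information (nats) of a contingency table
mutual_information <- function(ct) {
  nij <- ct$counts; n <- ct$n
  a <- rowSums(nij); b <- colSums(nij)
  idx <- which(nij > 0, arr.ind = TRUE)
  vals <- nij[idx]
  sum(vals / n * (log(vals) + log(n) - log(a[idx[, 1]]) - log(b[idx[, 2]])))
}

#' Exact expected mutual information under the permutation null
#'
#' The expectation of the mutual information between two partitions with
#' the observed marginals, under random labelings with those marginals
#' fixed (hypergeometric model). Computed by the exact closed-form sum over
#' all feasible cell counts, with log-gamma arithmetic for stability.
#'
#' @param ct a [contingency_table()]
#' @return E\{MI\} in nats
#' @export
expected_mutual_information <- function(ct) {
  a <- rowSums(ct$counts); b <- colSums(ct$counts); n <- ct$n
  emi <- 0
  lgn <- lgamma(n + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      term <- nij / n * (log(nij) + log(n) - log(ai) - log(bj))
      lw <- lgamma(ai + 1) + lgamma(bj + 1) +
        lgamma(n - ai + 1) + lgamma(n - bj + 1) - lgn -
        lgamma(nij + 1) - lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum(term * exp(lw))
    }
  }
  emi
}

#' Adjusted mutual information between two partitions
#'
#' `AMI = (MI - E{MI}) / (max(H(U), H(V)) - E{MI})`, where the expectation
#' is exact under the permutation (fixed-marginals hypergeometric) null.
#' The score is 1 for identical non-trivial partitions and about 0 for
#' independent ones. Samples carrying the noise label `-1` in either
#' partition are excluded pairwise before computing the table. Degenerate
#' denominators (e.g. both partitions trivial) return 0.
#'
#' @param u,v label vectors or [cluster_assignment()]s over the same samples
#' @return AMI value (<= 1; can be slightly negative by chance)
#' @export
adjusted_mutual_information <- function(u, v) {
  u <- as_label_vector(u); v <- as_label_vector(v)
  stopifnot(length(u) == length(v))
  keep <- u != -1L & v != -1L
  u <- u[keep]; v <- v[keep]
  if (!length(u)) return(0)
  ct <- contingency_table(u, v)
  hu <- partition_entropy(u); hv <- partition_entropy(v)
  mi <- mutual_information(ct)
  emi <- expected_mutual_information(ct)
  denom <- max(hu, hv) - emi
  if (abs(denom) < 1e-12) return(0)
  (mi - emi) / denom
}

#' V-measure against a partial reference labeling
#'
#' Entropy-based agreement between a reference class labeling and a
#' predicted clustering, evaluated only on samples whose reference label is
#' not [NO_DIAGNOSIS] (and whose prediction is not noise). Homogeneity
#' `h = 1 - H(C|K)/H(C)` rewards clusters containing a single reference
#' class; completeness `c = 1 - H(K|C)/H(K)` rewards classes concentrated
#' in a single cluster (`h = 1` when `H(C) = 0`, `c = 1` when `H(K) = 0`).
#' The V-measure is their weighted harmonic mean
#' `(1 + beta) h c / (beta h + c)`; `beta < 1` emphasizes homogeneity.
#'
#' @param reference character vector of class labels, [NO_DIAGNOSIS] (or
#'   `NA`) marking unlabeled samples
#' @param predicted a [cluster_assignment()] or label vector, aligned with
#'   `reference`
#' @param beta homogeneity/completeness weight (default 0.1)
#' @return a `v_measure_result`: list with `h`, `c`, `beta`, `v`,
#'   `n_evaluated`
#' @export
v_measure <- function(reference, predicted, beta = 0.1) {
  stopifnot(beta >= 0)
  reference <- as.character(reference)
  predicted <- as_label_vector(predicted)
  stopifnot(length(reference) == length(predicted))
  keep <- !is.na(reference) & reference != NO_DIAGNOSIS & predicted != -1L
  if (!any(keep)) stop("no reference labels to evaluate against")
  ref <- reference[keep]; pred <- predicted[keep]
  ct <- contingency_table(ref, pred)
  hc <- partition_entropy(ref)       # H(C)
  hk <- partition_entropy(pred)      # H(K)
  mi <- mutual_information(ct)
  h <- if (hc == 0) 1 else mi / hc   # 1 - H(C|K)/H(C)
  c_ <- if (hk == 0) 1 else mi / hk  # 1 - H(K|C)/H(K)
  v <- if (beta * h + c_ == 0) 0 else (1 + beta) * h * c_ / (beta * h + c_)
  structure(list(h = h, c = c_, beta = beta, v = v,
                 n_evaluated = sum(keep)),
            class = "v_measure_result")
}

#' @export
print.v_measure_result <- function(x, ...) {
  cat(sprintf(
    "v_measure: v = %.4f (h = %.4f, c = %.4f, beta = %g, n = %d)\n",
    x$v, x$h, x$c, x$beta, x$n_evaluated))
  invisible(x)
}

#' Mean silhouette of a clustering
#'
#' Mean over samples of `(b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to the sample's own cluster and `b` the smallest mean distance
#' to another cluster, computed in the embedding (clustering) space.
#' Samples in singleton clusters score 0; noise samples are excluded.
#'
#' @param embedding an `embedding` (or numeric matrix)
#' @param assignment a [cluster_assignment()] with at least 2 non-noise
#'   clusters
#' @return mean silhouette in `[-1, 1]`
#' @export
silhouette_mean <- function(embedding, assignment) {
  x <- embedding_coords(embedding)
  labels <- as_label_vector(assignment)
  stopifnot(nrow(x) == length(labels))
  keep <- labels != -1L
  labels <- labels[keep]; x <- x[keep, , drop = FALSE]
  if (length(unique(labels)) < 2)
    stop("silhouette requires at least 2 non-noise clusters")
  sil <- cluster::silhouette(labels, stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Four-clustering stability of an inductive clusterer
#'
#' The bootstrap stability protocol for k-means: fit the clusterer on each
#' half of a partitioning (both halves already reduced with identical
#' hyperparameters), apply both fitted models to both halves, and compare
#' the two clusterings of the same half with the AMI. The final score is
#' the mean of the train-half and test-half AMIs.
#'
#' @param train_emb,test_emb `embedding`s (or matrices) of the two halves,
#'   same method and dimensionality
#' @param k number of k-means clusters
#' @param seed integer seed used for both fits
#' @param n_init k-means restarts per fit
#' @return a `stability_result`: list with `kind = "ami_average"`, `value`,
#'   `components` (the two per-half AMIs), plus the four assignments and
#'   the two models
#' @export
stability_inductive <- function(train_emb, test_emb, k, seed = 1L,
                                n_init = 10) {
  xt <- embedding_coords(train_emb); xs <- embedding_coords(test_emb)
  if (ncol(xt) != ncol(xs))
    stop("train and test embeddings must share dimensionality")
  fit_tr <- fit_kmeans(xt, k, seed = seed, n_init = n_init)
  fit_te <- fit_kmeans(xs, k, seed = seed, n_init = n_init)
  tr_self <- fit_tr$assignment
  tr_cross <- predict_kmeans(fit_te$model, xt)
  te_self <- fit_te$assignment
  te_cross <- predict_kmeans(fit_tr$model, xs)
  ami_tr <- adjusted_mutual_information(tr_self, tr_cross)
  ami_te <- adjusted_mutual_information(te_self, te_cross)
  structure(list(kind = "ami_average",
                 value = mean(c(ami_tr, ami_te)),
                 components = c(train = ami_tr, test = ami_te),
                 fit_train = fit_tr, fit_test = fit_te),
            class = "stability_result")
}

#' Cluster-count stability of a transductive clusterer
#'
#' DBSCAN cannot label unseen samples, so its four-clustering AMI protocol
#' is replaced by the absolute difference in the number of (non-noise)
#' clusters found on the two halves under identical hyperparameters.
#'
#' @param train_assign,test_assign [cluster_assignment()]s from the same
#'   DBSCAN hyperparameters on the two halves
#' @return a `stability_result` with `kind = "cluster_count_diff"`
#' @export
stability_transductive <- function(train_assign, test_assign) {
  structure(list(kind = "cluster_count_diff",
                 value = abs(train_assign$n_clusters -
                               test_assign$n_clusters),
                 components = c(train = train_assign$n_clusters,
                                test = test_assign$n_clusters)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  if (x$kind == "ami_average")
    cat(sprintf("stability: averaged AMI = %.4f (train %.4f, test %.4f)\n",
                x$value, x$components[["train"]], x$components[["test"]]))
  else
    cat(sprintf("stability: cluster count difference = %d (%d vs %d)\n",
                x$value, x$components[["train"]], x$components[["test"]]))
  invisible(x)
}
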