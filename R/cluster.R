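#' Cluster assignment container
#'
#' Integer cluster labels per sample: non-noise clusters are the
#' consecutive integers `0 .. n_clusters - 1`, and `-1` is reserved for
#' DBSCAN noise. Construction relabels arbitrary input labels to this
#' canonical form by descending cluster size (ties by first appearance).
#'
#' @param labels integer-ish vector; `-1` (or `NA`) marks noise
#' @param source optional provenance list (method, hyperparameters)
#' @return a `cluster_assignment`: list with `labels`, `n_clusters`,
#'   `source`
#' @export
cluster_assignment <- function(labels, source = NULL) {
  labels <- as.integer(labels)
  labels[is.na(labels)] <- -1L
  keep <- labels != -1L
  if (any(keep)) {
    sizes <- table(labels[keep])
    ord <- names(sizes)[order(-as.integer(sizes),
                              match(names(sizes), names(sizes)))]
    remap <- stats::setNames(seq_along(ord) - 1L, ord)
    labels[keep] <- remap[as.character(labels[keep])]
  }
  structure(list(labels = labels,
                 n_clusters = length(unique(labels[keep])),
                 source = source),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples, %d clusters, %d noise\n",
              length(x$labels), x$n_clusters, sum(x$labels == -1L)))
  invisible(x)
}

embedding_coords <- function(embedding) {
  if (inherits(embedding, "embedding")) embedding$coordinates
  else as.matrix(embedding)
}

# squared Euclidean distances from each row of x to each row of centers
dist2_to_centers <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center with probability proportional to the squared distance
# to the closest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) <= 0) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Fit k-means in an embedding space
#'
#' Squared-Euclidean k-means with k-means++ seeding, keeping the
#' best-inertia solution over `n_init` seeded restarts. Cluster labels are
#' canonicalized to consecutive integers `0 .. k-1` by descending cluster
#' size, and the returned centroids are reordered accordingly so that
#' [predict_kmeans()] on the fitting data reproduces the fit labels.
#'
#' @param embedding an `embedding` (or numeric matrix)
#' @param k number of clusters, 2 to `n_samples`
#' @param seed integer seed
#' @param n_init number of k-means++ restarts (default 10)
#' @return list with `model` (a `cluster_model`: centroids, k, seed) and
#'   `assignment` (a [cluster_assignment()])
#' @export
fit_kmeans <- function(embedding, k, seed = 1L, n_init = 10) {
  x <- embedding_coords(embedding)
  if (k > nrow(x)) stop("k (", k, ") exceeds number of samples (", nrow(x), ")")
  if (k < 1) stop("k must be >= 1")
  set.seed(as.integer(seed))
  best <- NULL
  for (i in seq_len(n_init)) {
    init <- kmeanspp_init(x, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)  # a restart can empty a cluster; skip it
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) best <- fit
  }
  if (is.null(best))
    stop("k-means failed for all ", n_init, " restarts (k = ", k, ")")
  # canonical order: descending size, ties by original cluster index
  ord <- order(-best$size, seq_along(best$size))
  centers <- best$centers[ord, , drop = FALSE]
  rownames(centers) <- NULL
  model <- structure(list(method = "kmeans", centroids = centers,
                          k = as.integer(k), seed = as.integer(seed),
                          inertia = best$tot.withinss),
                     class = "cluster_model")
  relabel <- match(seq_along(ord), ord) - 1L
  labels <- relabel[best$cluster]
  assignment <- structure(
    list(labels = as.integer(labels), n_clusters = as.integer(k),
         source = list(method = "kmeans", k = k, seed = seed)),
    class = "cluster_assignment")
  list(model = model, assignment = assignment)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k-means, k=%d, %d-dimensional, inertia %.4g\n",
              x$k, ncol(x$centroids), x$inertia))
  invisible(x)
}

#' Assign samples to the nearest k-means centroid
#'
#' Squared-Euclidean nearest-centroid rule; exact ties go to the
#' lowest-index centroid.
#'
#' @param model a `cluster_model` from [fit_kmeans()]
#' @param embedding an `embedding` (or matrix) with the same dimensionality
#'   as the centroids
#' @return a [cluster_assignment()]
#' @export
predict_kmeans <- function(model, embedding) {
  x <- embedding_coords(embedding)
  if (ncol(x) != ncol(model$centroids))
    stop("embedding dimensionality (", ncol(x),
         ") does not match centroids (", ncol(model$centroids), ")")
  d2 <- dist2_to_centers(x, model$centroids)
  labels <- max.col(-d2, ties.method = "first") - 1L
  structure(list(labels = as.integer(labels),
                 n_clusters = model$k,
                 source = list(method = "kmeans", k = model$k,
                               seed = model$seed, predicted = TRUE)),
            class = "cluster_assignment")
}

#' Density-based clustering (DBSCAN)
#'
#' Classic density-reachability clustering: points with at least
#' `min_samples` neighbors within `eps` (the point itself included) are
#' core points; clusters are the connected components of core points at
#' range `eps`; non-core points within `eps` of a core point join the
#' cluster of their nearest such core, and all remaining points are noise
#' (label `-1`). Assignments are invariant to the input row order up to
#' cluster relabeling.
#'
#' @param embedding an `embedding` (or numeric matrix)
#' @param eps neighborhood radius, > 0
#' @param min_samples minimum neighborhood size for a core point
#' @return a [cluster_assignment()]; `n_clusters` counts non-noise
#'   clusters only
#' @export
fit_dbscan <- function(embedding, eps, min_samples = 5) {
  if (eps <= 0) stop("eps must be > 0")
  x <- embedding_coords(embedding)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nbr <- d <= eps
  core <- rowSums(nbr) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  visited <- rep(FALSE, n)
  for (i in which(core)) {
    if (visited[i]) next
    # flood fill over core points
    comp <- i; visited[i] <- TRUE; frontier <- i
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(j)
        which(nbr[j, ] & core & !visited))))
      visited[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    labels[comp] <- cl
    cl <- cl + 1L
  }
  border <- which(!core & labels == -1L)
  for (i in border) {
    cores_near <- which(nbr[i, ] & core)
    if (length(cores_near))
      labels[i] <- labels[cores_near[which.min(d[i, cores_near])]]
  }
  cluster_assignment(labels, source = list(method = "dbscan", eps = eps,
                                           min_samples = min_samples))
}
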