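new_embedding <- function(coordinates, method, hyperparameters, seed = NA,
                          extra = list()) {
  stopifnot(all(is.finite(coordinates)))
  dimnames(coordinates) <- list(NULL, paste0("comp", seq_len(ncol(coordinates))))
  structure(c(list(coordinates = coordinates, method = method,
                   hyperparameters = hyperparameters, seed = seed), extra),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat(sprintf("embedding: %s (%s), %d samples x %d components\n",
              x$method, hp, nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

# Fix each component's sign so the loading with the largest magnitude is
# positive. Without this, two halves of the same cohort can land in
# mirror-image spaces and cross-half centroid prediction (the stability
# protocol) would be meaningless.
canonicalize_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(scores))) {
    l <- loadings[, j]
    if (l[which.max(abs(l))] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis of an encoded table
#'
#' Projects the (already standardized) encoded matrix onto its top-variance
#' pairwise-orthogonal axes. Component signs are canonicalized (largest
#' absolute loading positive) so that independently reduced halves of a
#' cohort live in comparable spaces.
#'
#' @param encoded an `encoded_matrix` from [encode()], or a plain numeric
#'   matrix
#' @param n_components number of components, between 2 and the number of
#'   columns
#' @return an `embedding` with extra fields `loadings` and `sdev`
#' @export
reduce_pca <- function(encoded, n_components = 2) {
  x <- if (inherits(encoded, "encoded_matrix")) encoded$values else encoded
  if (n_components > ncol(x))
    stop("n_components (", n_components, ") exceeds number of columns (",
         ncol(x), ")")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  sc <- canonicalize_signs(p$x[, seq_len(n_components), drop = FALSE],
                           p$rotation[, seq_len(n_components), drop = FALSE])
  new_embedding(sc$scores, "pca", list(n_components = n_components),
                extra = list(loadings = sc$loadings,
                             sdev = p$sdev[seq_len(n_components)],
                             total_var = sum(p$sdev^2)))
}

# FAMD working matrix: quantitative columns z-scored, categorical levels as
# indicators divided by sqrt(level proportion), all centered by prcomp.
famd_matrix <- function(table) {
  cols <- list()
  for (nm in names(table$data)) {
    x <- table$data[[nm]]
    if (table$kinds[[nm]] == "quantitative") {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) s <- 1
      cols[[nm]] <- (x - mean(x)) / s
    } else {
      if (nlevels(droplevels(x)) < 2)
        stop("categorical feature '", nm,
             "' has a single observed level; FAMD weighting is degenerate")
      for (lv in levels(x)) {
        p <- mean(x == lv)
        if (p > 0) cols[[paste0(nm, "=", lv)]] <- as.numeric(x == lv) / sqrt(p)
      }
    }
  }
  do.call(cbind, cols)
}

#' Factor analysis of mixed data
#'
#' A PCA-like decomposition that consumes the raw mixed table:
#' quantitative columns are standardized and categorical levels enter as
#' indicator columns weighted by the inverse square root of the level
#' proportion, all centered before the eigendecomposition. On an
#' all-quantitative table the result coincides with [reduce_pca()] on the
#' standardized matrix; on an all-categorical table it matches multiple
#' correspondence analysis up to the scaling convention.
#'
#' @param table a fully imputed [patient_table()]
#' @param n_components number of components (>= 2)
#' @return an `embedding`
#' @export
reduce_famd <- function(table, n_components = 2) {
  if (any(missing_mask(table)))
    stop("table still contains missing cells; impute first")
  z <- famd_matrix(table)
  if (n_components > ncol(z))
    stop("n_components (", n_components, ") exceeds FAMD column count (",
         ncol(z), ")")
  p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  sc <- canonicalize_signs(p$x[, seq_len(n_components), drop = FALSE],
                           p$rotation[, seq_len(n_components), drop = FALSE])
  new_embedding(sc$scores, "famd", list(n_components = n_components),
                extra = list(sdev = p$sdev[seq_len(n_components)]))
}

# deterministic early-exaggeration t-SNE initialization: sign-canonicalized
# PCA scaled to sd 1e-4 (the conventional "pca" init)
tsne_init <- function(x, d) {
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
  sc <- canonicalize_signs(p$x[, seq_len(d), drop = FALSE],
                           p$rotation[, seq_len(d), drop = FALSE])
  y <- sc$scores
  y / stats::sd(y[, 1]) * 1e-4
}

#' t-distributed stochastic neighbor embedding
#'
#' A deterministic t-SNE run: input similarities calibrated to the given
#' perplexity, Student-t low-dimensional kernel, and a sign-canonicalized
#' PCA initialization (scaled to sd 1e-4). Because the initialization is a
#' deterministic function of the data, two independently embedded halves of
#' a cohort come out in comparable orientations, which the four-clustering
#' stability protocol requires. For 2-3 components the Barnes-Hut
#' approximation (theta = 0.5) is used; higher component counts fall back
#' to the exact O(n^2) gradient.
#'
#' @param encoded an `encoded_matrix` or numeric matrix
#' @param n_components output dimensionality, 2 to 6
#' @param perplexity t-SNE perplexity; must satisfy `3 * perplexity <
#'   n_samples - 1`
#' @param seed integer seed (kept for provenance; the run is deterministic)
#' @param max_iter gradient-descent iterations (default 1000)
#' @return an `embedding`
#' @export
reduce_tsne <- function(encoded, n_components = 2, perplexity = 30,
                        seed = 1L, max_iter = 1000) {
  x <- if (inherits(encoded, "encoded_matrix")) encoded$values else encoded
  n <- nrow(x)
  if (n < 10) stop("t-SNE requires at least 10 samples")
  if (n_components < 2 || n_components > 6)
    stop("n_components must be between 2 and 6")
  if (perplexity >= n)
    stop("perplexity (", perplexity, ") must be smaller than the number of samples (", n, ")")
  if (3 * perplexity > n - 1)
    stop("perplexity (", perplexity, ") too large for ", n,
         " samples (need 3 * perplexity <= n - 1)")
  y0 <- tsne_init(x, n_components)
  set.seed(as.integer(seed))
  if (n_components <= 3) {
    fit <- Rtsne::Rtsne(x, dims = n_components, perplexity = perplexity,
                        theta = 0.5, max_iter = max_iter, Y_init = y0,
                        check_duplicates = FALSE, pca = FALSE,
                        num_threads = 1)
    y <- fit$Y
  } else {
    y <- tsne_exact(x, y0, perplexity = perplexity, max_iter = max_iter)
  }
  new_embedding(y, "tsne",
                list(n_components = n_components, perplexity = perplexity),
                seed = seed)
}

# Exact (dense) t-SNE gradient descent, used for output dimensionalities
# the Barnes-Hut tree does not support. Standard recipe: perplexity-
# calibrated symmetrized input affinities, early exaggeration (12x for the
# first 100 iterations), momentum 0.5 -> 0.8, learning rate 200.
tsne_exact <- function(x, y, perplexity, max_iter = 500) {
  n <- nrow(x)
  P <- tsne_affinities(x, perplexity)
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  eta <- 200; mom <- 0.5
  upd <- matrix(0, n, ncol(y))
  gains <- matrix(1, n, ncol(y))
  Pe <- P * 12
  for (iter in seq_len(max_iter)) {
    if (iter == 101) Pe <- P
    if (iter == 21) mom <- 0.8
    d2 <- as.matrix(stats::dist(y))^2
    W <- 1 / (1 + d2); diag(W) <- 0
    Q <- W / sum(W)
    L <- (Pe - Q) * W
    G <- 4 * (diag(rowSums(L)) - L) %*% y
    gains <- ifelse(sign(G) != sign(upd), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    upd <- mom * upd - eta * gains * G
    y <- y + upd
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

# Row-wise binary search of Gaussian bandwidths matching log(perplexity)
tsne_affinities <- function(x, perplexity, tol = 1e-5) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { h <- 0 } else {
        p <- p / sp
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < tol) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}
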