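test_that("PCA captures planar structure and keeps components orthogonal and nested", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  x <- matrix(rnorm(200), 100, 2) %*% t(basis)  # exactly 2-D in 5-D
  e2 <- reduce_pca(x, 2)
  expect_lt(abs(sum(e2$sdev^2) / e2$total_var - 1), 1e-10)
  expect_lt(max(abs(crossprod(e2$loadings) - diag(2))), 1e-8)
  y <- matrix(rnorm(500), 100, 5)
  v2 <- sum(reduce_pca(y, 2)$sdev^2)
  v3 <- sum(reduce_pca(y, 3)$sdev^2)
  expect_gte(v3, v2)
  expect_error(reduce_pca(y, 6), "exceeds")
})

test_that("FAMD equals PCA on all-quantitative tables and MCA on all-categorical ones", {
  tab <- quant_table(n = 40, p = 5, seed = 2)
  f <- reduce_famd(tab, 3)
  p <- reduce_pca(encode(tab), 3)
  expect_equal(f$coordinates, p$coordinates, tolerance = 1e-10)

  # independent MCA oracle: correspondence analysis of the indicator matrix
  set.seed(4)
  d <- data.frame(g1 = factor(sample(c("a", "b", "c"), 60, TRUE)),
                  g2 = factor(sample(c("u", "v"), 60, TRUE)),
                  g3 = factor(sample(c("x", "y"), 60, TRUE)))
  tabc <- patient_table(d)
  f2 <- reduce_famd(tabc, 2)
  Z <- do.call(cbind, lapply(d, function(col)
    sapply(levels(col), function(lv) as.numeric(col == lv))))
  n <- nrow(Z); J <- ncol(d)
  P <- Z / (n * J)
  r <- rowSums(P); cmass <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %*% t(cmass)) %*% diag(1 / sqrt(cmass))
  sv <- svd(S)
  mca_rows <- diag(1 / sqrt(r)) %*% sv$u[, 1:2] %*% diag(sv$d[1:2])
  for (j in 1:2)
    expect_gt(abs(cor(f2$coordinates[, j], mca_rows[, j])), 0.999)

  # duplicated rows receive identical coordinates
  d2 <- rbind(d, d[1, ])
  f3 <- reduce_famd(patient_table(d2), 2)
  expect_equal(f3$coordinates[61, ], f3$coordinates[1, ], tolerance = 1e-8)

  # single observed level is degenerate
  d3 <- data.frame(g = factor(rep("a", 20), levels = c("a", "b")),
                   q = rnorm(20))
  expect_error(reduce_famd(patient_table(d3), 2), "single observed level")
})

test_that("t-SNE separates well-separated blobs and is bitwise deterministic", {
  set.seed(5)
  x <- rbind(matrix(rnorm(300), 75, 4),
             matrix(rnorm(300) + 10, 75, 4))
  blob <- rep(0:1, each = 75)
  e <- reduce_tsne(x, 2, perplexity = 30, seed = 9)
  expect_gt(silhouette_mean(e, cluster_assignment(blob)), 0.5)
  e2 <- reduce_tsne(x, 2, perplexity = 30, seed = 9)
  expect_identical(e$coordinates, e2$coordinates)
  expect_error(reduce_tsne(x, 2, perplexity = 150, seed = 1), "perplexity")
  expect_error(reduce_tsne(x, 2, perplexity = 200, seed = 1), "perplexity")
})

test_that("the exact gradient path (components > 3) is finite, deterministic and structured", {
  set.seed(6)
  x <- rbind(matrix(rnorm(200), 50, 4),
             matrix(rnorm(200) + 8, 50, 4))
  e <- reduce_tsne(x, 4, perplexity = 15, seed = 2, max_iter = 300)
  expect_true(all(is.finite(e$coordinates)))
  expect_identical(dim(e$coordinates), c(100L, 4L))
  e2 <- reduce_tsne(x, 4, perplexity = 15, seed = 2, max_iter = 300)
  expect_identical(e$coordinates, e2$coordinates)
  expect_gt(silhouette_mean(e, cluster_assignment(rep(0:1, each = 50))), 0.5)
})

test_that("k-means recovers point pairs, respects nesting, and is a prediction fixed point", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  fit <- fit_kmeans(x, 2, seed = 1)
  expect_setequal(split(seq_len(4), fit$assignment$labels),
                  list(1:2, 3:4))
  expect_equal(fit$model$centroids[order(fit$model$centroids[, 1]), ],
               rbind(c(0, 0.5), c(10, 0.5)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # k = n: inertia 0
  fit_n <- fit_kmeans(x, 4, seed = 1)
  expect_equal(fit_n$model$inertia, 0)
  # inertia never increases with k (best of n_init)
  set.seed(2); y <- matrix(rnorm(400), 100, 4)
  inertias <- vapply(2:6, function(k)
    fit_kmeans(y, k, seed = 3)$model$inertia, numeric(1))
  expect_true(all(diff(inertias) <= 1e-9))
  # fixed point: predicting the fitting data reproduces the fit labels
  fit_y <- fit_kmeans(y, 4, seed = 5)
  expect_identical(predict_kmeans(fit_y$model, y)$labels,
                   fit_y$assignment$labels)
  expect_error(fit_kmeans(x, 5, seed = 1), "exceeds")
})

test_that("k-means prediction breaks exact ties toward the lowest cluster index", {
  model <- structure(list(method = "kmeans",
                          centroids = rbind(c(-1, 0), c(1, 0)),
                          k = 2L, seed = 1L), class = "cluster_model")
  pred <- predict_kmeans(model, rbind(c(0, 5), c(-1, 0)))
  expect_identical(pred$labels, c(0L, 0L))  # equidistant point -> label 0
  expect_error(predict_kmeans(model, matrix(0, 1, 3)), "dimensionality")
})

test_that("DBSCAN finds dense blobs, flags isolated points, chains at range", {
  set.seed(7)
  x <- rbind(matrix(rnorm(60, sd = 0.2), 30, 2),
             matrix(rnorm(60, sd = 0.2) + 5, 30, 2),
             c(50, 50))  # isolated point
  a <- fit_dbscan(x, eps = 1, min_samples = 3)
  expect_identical(a$n_clusters, 2L)
  expect_identical(a$labels[61], -1L)
  # collinear chain spaced 0.5 apart with eps 0.6: density-reachable as one
  chain <- cbind(seq(0, 3, by = 0.5), 0)
  expect_identical(fit_dbscan(chain, eps = 0.6, min_samples = 2)$n_clusters, 1L)
  expect_error(fit_dbscan(x, eps = 0), "eps")
})

test_that("DBSCAN assignments are invariant to row order up to relabeling", {
  set.seed(8)
  x <- rbind(matrix(rnorm(80, sd = 0.3), 40, 2),
             matrix(rnorm(80, sd = 0.3) + 4, 40, 2),
             matrix(runif(20, -10, 10), 10, 2))
  a <- fit_dbscan(x, eps = 1, min_samples = 4)
  perm <- sample.int(nrow(x))
  b <- fit_dbscan(x[perm, ], eps = 1, min_samples = 4)
  keep <- a$labels[perm] != -1L & b$labels != -1L
  expect_identical(a$labels[perm] == -1L, b$labels == -1L)
  expect_equal(adjusted_mutual_information(a$labels[perm][keep],
                                           b$labels[keep]), 1)
})
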