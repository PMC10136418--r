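# Independent oracles and fixtures shared across the suite.

# Monte-Carlo estimate of the expected mutual information under the
# fixed-marginals permutation null. Deliberately independent of the
# package's closed-form hypergeometric sum: it shuffles one labeling and
# recomputes MI from scratch each time.
mc_expected_mi <- function(u, v, B = 1e5L) {
  u <- as.integer(factor(u)); v <- as.integer(factor(v))
  n <- length(u); J <- max(u); K <- max(v)
  base <- (u - 1L) * K
  a <- tabulate(u, J); b <- tabulate(v, K)
  la <- log(a); lb <- log(b); ln <- log(n)
  out <- numeric(B)
  for (bb in seq_len(B)) {
    joint <- tabulate(base + v[sample.int(n)], J * K)
    nz <- which(joint > 0L)
    nij <- joint[nz]
    i <- ((nz - 1L) %/% K) + 1L
    j <- ((nz - 1L) %% K) + 1L
    out[bb] <- sum(nij / n * (log(nij) + ln - la[i] - lb[j]))
  }
  c(mean = mean(out), se = stats::sd(out) / sqrt(B))
}

# two halves of k well-separated Gaussian blobs in 2-D
gaussian_half <- function(n, k = 3, sep = 8) {
  g <- sample(seq_len(k), n, replace = TRUE)
  centers <- cbind(sep * cos(2 * pi * seq_len(k) / k),
                   sep * sin(2 * pi * seq_len(k) / k))
  list(x = centers[g, , drop = FALSE] + matrix(stats::rnorm(2 * n), n),
       g = g)
}

# small all-quantitative patient table
quant_table <- function(n = 30, p = 4, seed = 1) {
  set.seed(seed)
  patient_table(as.data.frame(matrix(stats::rnorm(n * p), n,
                                     dimnames = list(NULL, paste0("q", 1:p)))))
}

# mixed table with known correlated structure (for imputation tests):
# q2-q5 are noisy linear functions of q1, and the categorical tracks the
# sign of q1; enough columns that MCAR holes leave every row partly
# observed
correlated_table <- function(n = 300, seed = 1) {
  set.seed(seed)
  q1 <- stats::rnorm(n)
  q2 <- 2 * q1 + stats::rnorm(n, sd = 0.3)
  q3 <- -q1 + stats::rnorm(n, sd = 0.3)
  q4 <- q1 + stats::rnorm(n, sd = 0.5)
  q5 <- 0.5 * q1 + stats::rnorm(n, sd = 0.5)
  cc <- factor(ifelse(q1 + stats::rnorm(n, sd = 0.3) > 0, "hi", "lo"))
  patient_table(data.frame(q1 = q1, q2 = q2, q3 = q3, q4 = q4, q5 = q5,
                           cc = cc))
}

# how many endotypes end up "majority-distinct": the cluster holding the
# plurality of an endotype's members has that endotype as its majority
# label among ground-truth-labeled members
count_separated <- function(truth, cluster_labels) {
  sep <- 0
  for (e in unique(truth[truth != NO_DIAGNOSIS])) {
    home <- names(which.max(table(cluster_labels[truth == e])))
    in_home <- truth[cluster_labels == as.integer(home) &
                       truth != NO_DIAGNOSIS]
    maj <- names(sort(table(in_home), decreasing = TRUE))[1]
    if (identical(maj, e)) sep <- sep + 1
  }
  sep
}

# reduced-scale planted-endotype benchmark used by the end-to-end checks
run_reduced_benchmark <- function(n = 2000, seed = 1) {
  spec <- tinnitus_cohort_spec(n_patients = n)
  co <- generate_cohort(spec, seed = seed)
  splits <- stratified_splits(co$labels, 3, seed = seed + 1000L)
  grid <- grid_spec(pca_components = 2, tsne_components = 2,
                    tsne_perplexity = c(30, 75), kmeans_k = c(4, 6, 8, 10))
  recs <- run_benchmark(co$table, splits, grid, seed = seed + 2000L,
                        reductions = c("pca", "tsne"),
                        clusterers = "kmeans")
  list(cohort = co, splits = splits, records = recs)
}
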