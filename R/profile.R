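#' Characterize clusters by pooled Cohen's D effect sizes
#'
#' For every (non-noise) cluster and every feature, compares the cluster's
#' patients against all remaining patients with the pooled Cohen's D:
#' `D = (mean_in - mean_out) / s_pooled`,
#' `s_pooled = sqrt(((n_in - 1) s_in^2 + (n_out - 1) s_out^2) /
#' (n_in + n_out - 2))`. Categorical features enter as one 0/1 indicator
#' per level. Features with `D >= d_threshold` are listed as positive
#' differentiation, those with `D <= -d_threshold` as negative, sorted by
#' `|D|` within each cluster. A feature whose means differ while the
#' pooled variance is zero (a perfectly separating indicator) gets an
#' infinite D, reported as `">10"` by [format_effect_size()]; a constant
#' feature gets `D = 0` and is listed nowhere.
#'
#' @param table a [patient_table()] aligned with `assignment`
#' @param assignment a [cluster_assignment()]
#' @param d_threshold minimum `|D|` to report (default 0.3)
#' @return a `cluster_profiles` data.frame: cluster, size, feature, d,
#'   direction
#' @export
profile_clusters <- function(table, assignment, d_threshold = 0.3) {
  labels <- as_label_vector(assignment)
  stopifnot(n_patients(table) == length(labels))
  if (any(missing_mask(table)))
    stop("table still contains missing cells; impute first")

  # numeric view: quantitative native, categorical as 0/1 indicators
  cols <- list()
  for (nm in names(table$data)) {
    x <- table$data[[nm]]
    if (table$kinds[[nm]] == "quantitative") cols[[nm]] <- x
    else for (lv in levels(droplevels(x)))
      cols[[paste0(nm, "=", lv)]] <- as.numeric(x == lv)
  }
  mat <- do.call(cbind, cols)

  clusters <- sort(unique(labels[labels != -1L]))
  rows <- list()
  for (cl in clusters) {
    inside <- labels == cl
    outside <- labels != cl & labels != -1L
    n_in <- sum(inside); n_out <- sum(outside)
    if (n_in < 2 || n_out < 2) next
    m_in <- colMeans(mat[inside, , drop = FALSE])
    m_out <- colMeans(mat[outside, , drop = FALSE])
    v_in <- apply(mat[inside, , drop = FALSE], 2, stats::var)
    v_out <- apply(mat[outside, , drop = FALSE], 2, stats::var)
    s_pooled <- sqrt(((n_in - 1) * v_in + (n_out - 1) * v_out) /
                       (n_in + n_out - 2))
    diff <- m_in - m_out
    d <- ifelse(s_pooled > 0, diff / s_pooled,
                ifelse(abs(diff) > 1e-12, sign(diff) * Inf, 0))
    sel <- which(abs(d) >= d_threshold)
    if (!length(sel)) next
    sel <- sel[order(-abs(d[sel]))]
    rows[[length(rows) + 1]] <- data.frame(
      cluster = cl, size = n_in, feature = names(cols)[sel],
      d = unname(d[sel]),
      direction = ifelse(d[sel] > 0, "positive", "negative"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(cluster = integer(0), size = integer(0),
                         feature = character(0), d = numeric(0),
                         direction = character(0))
  rownames(out) <- NULL
  class(out) <- c("cluster_profiles", "data.frame")
  attr(out, "d_threshold") <- d_threshold
  out
}

#' Render an effect size for reporting
#'
#' Finite values print rounded to 2 digits; infinite values (zero pooled
#' variance with differing means, e.g. a perfectly separating indicator)
#' print as `">10"` / `"<-10"`.
#'
#' @param d numeric vector of Cohen's D values
#' @return character vector
#' @export
format_effect_size <- function(d) {
  ifelse(is.infinite(d), ifelse(d > 0, ">10", "<-10"),
         sprintf("%.2f", d))
}

#' Observed vs expected endotype counts per cluster
#'
#' Cross-tabulates the labeled patients of a clustering: for each (cluster,
#' endotype) pair, the observed number of labeled members, and the count
#' expected if that endotype's patients were assigned to the clusters
#' uniformly at random (endotype total divided by the number of clusters).
#' Noise samples are excluded.
#'
#' @param assignment a [cluster_assignment()]
#' @param labels character vector of partial endotype labels aligned with
#'   the assignment's samples
#' @param endotypes optional character vector of endotypes to tabulate;
#'   defaults to those present among the labels. An endotype absent from
#'   the subset gets observed 0 and expected 0 in every cluster.
#' @return data.frame: cluster, endotype, observed, expected
#' @export
endotype_repartition <- function(assignment, labels, endotypes = NULL) {
  lab_vec <- as_label_vector(assignment)
  labels <- as.character(labels)
  stopifnot(length(lab_vec) == length(labels))
  keep <- lab_vec != -1L
  lab_vec <- lab_vec[keep]; labels <- labels[keep]
  clusters <- sort(unique(lab_vec))
  n_clusters <- length(clusters)
  endos <- if (is.null(endotypes))
    sort(unique(labels[!is.na(labels) & labels != NO_DIAGNOSIS]))
  else endotypes
  rows <- list()
  for (e in endos) {
    total <- sum(labels == e, na.rm = TRUE)
    for (cl in clusters) {
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, endotype = e,
        observed = sum(lab_vec == cl & labels == e, na.rm = TRUE),
        expected = total / n_clusters,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(cluster = integer(0), endotype = character(0),
                         observed = integer(0), expected = numeric(0))
  rownames(out) <- NULL
  out
}
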