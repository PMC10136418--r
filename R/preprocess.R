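#' Remove patients with excessive missingness
#'
#' Drops every patient whose fraction of missing feature cells is strictly
#' greater than `max_missing` (the label column does not count). Run this
#' before [filter_features()]: the pipeline order patients -> features ->
#' imputation is part of the method's contract, and feature missingness is
#' assessed over the surviving patients only.
#'
#' @param table a [patient_table()]
#' @param max_missing tolerated missing fraction per patient, in (0, 1);
#'   default 0.40
#' @return the filtered table, patient order preserved
#' @export
filter_patients <- function(table, max_missing = 0.40) {
  stopifnot(max_missing > 0, max_missing < 1)
  frac <- rowMeans(missing_mask(table))
  keep <- frac <= max_missing
  if (!any(keep))
    stop("no patients survive the ", max_missing, " missingness filter")
  table[which(keep), ]
}

#' Remove features with excessive missingness
#'
#' Drops every feature whose missing fraction over the current patients is
#' strictly greater than `max_missing`. Labels are stored outside the
#' feature table and are never filtered.
#'
#' @param table a [patient_table()], typically after [filter_patients()]
#' @param max_missing tolerated missing fraction per feature, in (0, 1);
#'   default 0.25
#' @return the filtered table, feature order preserved
#' @export
filter_features <- function(table, max_missing = 0.25) {
  stopifnot(max_missing > 0, max_missing < 1)
  frac <- colMeans(missing_mask(table))
  keep <- frac <= max_missing
  if (!any(keep))
    stop("no features survive the ", max_missing, " missingness filter")
  table[, which(keep)]
}

#' Iterative random-forest imputation of missing cells
#'
#' Fills every missing cell in the style of the MissForest algorithm:
#' missing values are initialized with the column mean (quantitative) or
#' mode (categorical); then, visiting features in ascending order of
#' missingness, a random forest is fit on the rows where the feature is
#' observed (all other features as predictors) and its predictions
#' overwrite that feature's missing cells. The sweep repeats until the
#' normalized change in the imputed values stops decreasing (separately for
#' quantitative and categorical cells) or `max_iter` is reached, and the
#' values from the last improving sweep are returned. Observed cells are
#' never altered.
#'
#' @param table a [patient_table()]; every patient and every feature must
#'   have at least one observed value (apply the filters first)
#' @param max_iter maximum number of sweeps (default 10)
#' @param num_trees trees per forest (default 100)
#' @param seed integer seed; the procedure is deterministic given it
#' @return the table with all cells observed
#' @export
impute_missforest <- function(table, max_iter = 10, num_trees = 100,
                              seed = 1L) {
  mask <- missing_mask(table)
  if (!any(mask)) return(table)
  col_missing <- colSums(mask)
  if (any(col_missing == nrow(mask)))
    stop("feature(s) entirely missing: ",
         paste(colnames(mask)[col_missing == nrow(mask)], collapse = ", "),
         " - apply filter_features() first")
  if (any(rowSums(mask) == ncol(mask)))
    stop("some patients have no observed value - apply filter_patients() first")

  df <- table$data
  kinds <- table$kinds
  # initialize with column mean / mode
  for (nm in names(df)) {
    miss <- mask[, nm]
    if (!any(miss)) next
    if (kinds[[nm]] == "quantitative") {
      df[[nm]][miss] <- mean(df[[nm]][!miss])
    } else {
      tabl <- table(df[[nm]][!miss])
      df[[nm]][miss] <- names(tabl)[which.max(tabl)]
    }
  }

  visit <- names(sort(col_missing[col_missing > 0]))
  prev_df <- df
  prev_err <- c(quant = Inf, categ = Inf)
  for (iter in seq_len(max_iter)) {
    old_df <- df
    for (j in seq_along(visit)) {
      nm <- visit[[j]]
      miss <- mask[, nm]
      fit_df <- df[!miss, , drop = FALSE]
      fit_df$.target <- df[[nm]][!miss]
      fit_df[[nm]] <- NULL
      rf <- ranger::ranger(
        dependent.variable.name = ".target", data = fit_df,
        num.trees = num_trees, num.threads = 1,
        seed = as.integer(seed) + 131L * iter + j,
        respect.unordered.factors = "order")
      pred <- stats::predict(
        rf, data = df[miss, setdiff(names(df), nm), drop = FALSE],
        num.threads = 1)$predictions
      if (kinds[[nm]] == "categorical")
        pred <- factor(as.character(pred), levels = levels(df[[nm]]))
      df[[nm]][miss] <- pred
    }
    # normalized change over imputed cells since the previous sweep
    dq <- 0; sq <- 0; nc_changed <- 0; nc_total <- 0
    for (nm in visit) {
      miss <- mask[, nm]
      if (kinds[[nm]] == "quantitative") {
        dq <- dq + sum((df[[nm]][miss] - old_df[[nm]][miss])^2)
        sq <- sq + sum(df[[nm]][miss]^2)
      } else {
        nc_changed <- nc_changed + sum(df[[nm]][miss] != old_df[[nm]][miss])
        nc_total <- nc_total + sum(miss)
      }
    }
    err <- c(quant = if (sq > 0) dq / sq else 0,
             categ = if (nc_total > 0) nc_changed / nc_total else 0)
    if (sum(err) >= sum(prev_err)) { df <- prev_df; break }
    prev_df <- df
    prev_err <- err
  }
  table$data <- df
  table
}

#' Encode a mixed table as a numeric matrix
#'
#' Quantitative features are z-scored; categorical features are expanded to
#' one 0/1 indicator column per level (no reference level is dropped, so
#' distance-based methods weight all levels symmetrically). When
#' `fit_stats` (a previous encoding) is supplied, its centers/scales and
#' level sets are reused, i.e. the call acts as a transform; an unobserved
#' level then raises an error. A constant quantitative column is centered
#' and left at scale 1.
#'
#' @param table a fully imputed [patient_table()]
#' @param fit_stats optional `encoded_matrix` whose scaling to reuse
#' @return an `encoded_matrix`: list with `values` (numeric matrix),
#'   `column_map` (data.frame: column, feature, level), `center`, `scale`,
#'   `levels`
#' @export
encode <- function(table, fit_stats = NULL) {
  if (any(missing_mask(table)))
    stop("table still contains missing cells; impute first")
  kinds <- table$kinds
  cols <- list(); map_feature <- character(0); map_level <- character(0)
  center <- numeric(0); scale <- numeric(0); level_sets <- list()

  for (nm in names(table$data)) {
    x <- table$data[[nm]]
    if (kinds[[nm]] == "quantitative") {
      if (is.null(fit_stats)) {
        ctr <- mean(x)
        scl <- stats::sd(x)
        if (!is.finite(scl) || scl == 0) scl <- 1
      } else {
        if (!nm %in% names(fit_stats$center))
          stop("feature '", nm, "' absent from fit_stats")
        ctr <- fit_stats$center[[nm]]
        scl <- fit_stats$scale[[nm]]
      }
      cols[[nm]] <- (x - ctr) / scl
      map_feature <- c(map_feature, nm); map_level <- c(map_level, NA)
      center[nm] <- ctr; scale[nm] <- scl
    } else {
      levs <- if (is.null(fit_stats)) levels(x) else fit_stats$levels[[nm]]
      if (is.null(levs)) stop("feature '", nm, "' absent from fit_stats")
      if (!all(as.character(x) %in% levs))
        stop("feature '", nm, "' has level(s) unseen in fit_stats: ",
             paste(setdiff(unique(as.character(x)), levs), collapse = ", "))
      for (lv in levs) {
        cols[[paste0(nm, "=", lv)]] <- as.numeric(x == lv)
        map_feature <- c(map_feature, nm); map_level <- c(map_level, lv)
      }
      level_sets[[nm]] <- levs
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- table$ids
  structure(list(
    values = values,
    column_map = data.frame(column = colnames(values),
                            feature = map_feature, level = map_level,
                            stringsAsFactors = FALSE),
    center = center, scale = scale, levels = level_sets),
    class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("encoded_matrix: %d x %d (from %d features)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$column_map$feature))))
  invisible(x)
}
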