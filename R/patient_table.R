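#' Sentinel label for undiagnosed patients
#'
#' Patients without an expert endotype diagnosis carry this value in the
#' label vector of a [patient_table()]. It forms its own stratum in the
#' 50-50 partitionings and is excluded from the V-measure.
#'
#' @export
NO_DIAGNOSIS <- "no diagnosis"

#' Mixed-type patient feature table
#'
#' The central container of the pipeline: a patient-by-feature table mixing
#' quantitative (numeric) and categorical (factor) questionnaire features,
#' with `NA` marking missing cells, plus an optional partial endotype label
#' per patient ([NO_DIAGNOSIS] for the unlabeled majority).
#'
#' @param data data.frame of features; numeric columns are treated as
#'   quantitative, character/factor columns as categorical.
#' @param kinds optional named character vector (`"quantitative"` or
#'   `"categorical"`) overriding the inferred column kinds.
#' @param labels optional character vector of per-patient endotype labels;
#'   defaults to all-[NO_DIAGNOSIS].
#' @param ids optional unique patient identifiers.
#'
#' @return An object of class `patient_table`: a list with elements `data`
#'   (data.frame), `kinds`, `labels`, `ids`.
#' @export
patient_table <- function(data, kinds = NULL, labels = NULL, ids = NULL) {
  stopifnot(is.data.frame(data), ncol(data) >= 1)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(kinds)) {
    kinds <- vapply(data, function(x)
      if (is.numeric(x)) "quantitative" else "categorical", character(1))
  }
  if (is.null(names(kinds))) names(kinds) <- names(data)
  kinds <- kinds[names(data)]
  if (anyNA(kinds) || !all(kinds %in% c("quantitative", "categorical")))
    stop("`kinds` must map every column to 'quantitative' or 'categorical'")
  for (nm in names(data)) {
    if (kinds[[nm]] == "categorical" && !is.factor(data[[nm]]))
      data[[nm]] <- factor(data[[nm]])
    if (kinds[[nm]] == "quantitative" && !is.numeric(data[[nm]]))
      stop("column '", nm, "' declared quantitative but is not numeric")
  }
  n <- nrow(data)
  if (is.null(ids)) ids <- sprintf("P%05d", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  if (is.null(labels)) labels <- rep(NO_DIAGNOSIS, n)
  labels <- as.character(labels)
  if (length(labels) != n) stop("`labels` must have one entry per patient")
  labels[is.na(labels)] <- NO_DIAGNOSIS
  structure(list(data = data, kinds = kinds, labels = labels, ids = ids),
            class = "patient_table")
}

#' @export
dim.patient_table <- function(x) dim(x$data)

#' Number of patients in a table
#' @param table a [patient_table()]
#' @return integer count
#' @export
n_patients <- function(table) nrow(table$data)

#' Feature names of a patient table
#' @param table a [patient_table()]
#' @return character vector
#' @export
feature_names <- function(table) names(table$data)

#' Missingness mask of a patient table
#'
#' @param table a [patient_table()]
#' @return logical patients-by-features matrix, `TRUE` where the cell is
#'   missing. The label vector is not part of the mask.
#' @export
missing_mask <- function(table) {
  m <- is.na(as.matrix(table$data))
  dimnames(m) <- list(table$ids, names(table$data))
  m
}

#' Subset a patient table
#'
#' `x[i, j]` keeps patients `i` and features `j`, carrying labels and ids
#' along with the rows.
#'
#' @param x a [patient_table()]
#' @param i patient (row) index
#' @param j feature (column) index or names
#' @param ... ignored
#' @export
`[.patient_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$data))
  if (missing(j)) j <- seq_along(x$data)
  d <- x$data[i, j, drop = FALSE]
  # drop unused factor levels so downstream encodings see observed levels only
  patient_table(d, kinds = x$kinds[names(d)],
                labels = x$labels[i], ids = x$ids[i])
}

#' @export
print.patient_table <- function(x, ...) {
  nq <- sum(x$kinds == "quantitative")
  nc <- sum(x$kinds == "categorical")
  nl <- sum(x$labels != NO_DIAGNOSIS)
  cat(sprintf(
    "patient_table: %d patients x %d features (%d quantitative, %d categorical)\n",
    nrow(x$data), ncol(x$data), nq, nc))
  cat(sprintf("  labeled: %d (%.2f%%); missing cells: %.2f%%\n",
              nl, 100 * nl / nrow(x$data),
              100 * mean(is.na(as.matrix(x$data)))))
  invisible(x)
}

#' Write a patient table to CSV with a sidecar schema
#'
#' The CSV has one header row, an `id` column, one column per feature
#' (missing cells as empty strings) and a final `endotype` label column.
#' Column kinds and categorical levels are declared in a JSON schema written
#' next to the CSV (`<path>.schema.json`) so that the table round-trips
#' without type guessing.
#'
#' @param table a [patient_table()]
#' @param path CSV file path
#' @return `path`, invisibly
#' @export
write_patient_table <- function(table, path) {
  df <- data.frame(id = table$ids, stringsAsFactors = FALSE)
  for (nm in names(table$data)) {
    col <- table$data[[nm]]
    df[[nm]] <- if (is.factor(col)) as.character(col) else col
  }
  df$endotype <- table$labels
  utils::write.csv(df, path, row.names = FALSE, na = "")
  schema <- list(
    columns = lapply(names(table$data), function(nm) {
      col <- table$data[[nm]]
      if (table$kinds[[nm]] == "categorical")
        list(name = nm, kind = "categorical", levels = levels(col))
      else list(name = nm, kind = "quantitative")
    })
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a patient table written by [write_patient_table()]
#'
#' @param path CSV file path; the schema is read from `<path>.schema.json`
#'   unless `schema_path` is given.
#' @param schema_path optional explicit schema path
#' @return a [patient_table()]
#' @export
read_patient_table <- function(path, schema_path = paste0(path, ".schema.json")) {
  if (!file.exists(schema_path))
    stop("schema file not found: ", schema_path)
  schema <- jsonlite::read_json(schema_path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  ids <- df$id
  labels <- df$endotype
  data <- list()
  kinds <- character(0)
  for (colspec in schema$columns) {
    nm <- colspec$name
    raw <- df[[nm]]
    raw[raw == ""] <- NA
    if (colspec$kind == "categorical") {
      data[[nm]] <- factor(raw, levels = unlist(colspec$levels))
      kinds[nm] <- "categorical"
    } else {
      data[[nm]] <- as.numeric(raw)
      kinds[nm] <- "quantitative"
    }
  }
  patient_table(as.data.frame(data, check.names = FALSE),
                kinds = kinds, labels = labels, ids = ids)
}
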