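#' Endotype-stratified 50-50 train/test partitionings
#'
#' Draws `n_partitionings` independent partitionings of the cohort into two
#' halves. Within each partitioning every stratum (each endotype plus the
#' undiagnosed group) is shuffled and split half/half, so rare endotypes
#' are equally represented on both sides; when a stratum has an odd size,
#' the extra sample goes to the training side in odd-numbered partitionings
#' and to the test side in even-numbered ones. Each partitioning uses the
#' whole cohort: the halves are disjoint and exhaustive.
#'
#' @param labels character vector of per-patient endotype labels
#'   ([NO_DIAGNOSIS] for the unlabeled stratum), covering all patients
#' @param n_partitionings number of independent partitionings (default 3)
#' @param seed integer seed
#' @return a `split_set`: list with `partitionings` (list of
#'   `list(train, test)` integer index vectors), `strata`, `seed`
#' @export
stratified_splits <- function(labels, n_partitionings = 3, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  stopifnot(n >= 2, n_partitionings >= 1)
  strata <- split(seq_len(n), labels)
  if (any(lengths(strata) == 1))
    warning("stratum of size 1 (",
            paste(names(strata)[lengths(strata) == 1], collapse = ", "),
            "): assigned to the training side")
  set.seed(as.integer(seed))
  partitionings <- vector("list", n_partitionings)
  for (p in seq_len(n_partitionings)) {
    train <- integer(0); test <- integer(0)
    for (idx in strata) {
      m <- length(idx)
      if (m == 1) { train <- c(train, idx); next }
      sh <- idx[sample.int(m)]
      n_train <- m %/% 2 + (m %% 2) * (p %% 2)
      train <- c(train, sh[seq_len(n_train)])
      test <- c(test, sh[seq.int(n_train + 1, m)])
    }
    partitionings[[p]] <- list(train = sort(train), test = sort(test))
  }
  structure(list(partitionings = partitionings,
                 strata = labels, seed = as.integer(seed)),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("split_set: %d stratified 50-50 partitionings of %d patients\n",
              length(x$partitionings), length(x$strata)))
  for (p in seq_along(x$partitionings))
    cat(sprintf("  partitioning %d: train %d / test %d\n", p,
                length(x$partitionings[[p]]$train),
                length(x$partitionings[[p]]$test)))
  invisible(x)
}

#' Serialize a split set to JSON (0-based indices)
#'
#' @param splits a `split_set` from [stratified_splits()]
#' @param path JSON file path
#' @return `path` (write) or a `split_set` (read)
#' @export
write_split_set <- function(splits, path) {
  ser <- list(
    seed = splits$seed,
    strata = splits$strata,
    partitionings = lapply(splits$partitionings, function(p)
      list(train = p$train - 1L, test = p$test - 1L))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_set
#' @export
read_split_set <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    partitionings = lapply(seq_len(nrow0(y$partitionings)), function(i)
      list(train = as.integer(y$partitionings$train[[i]]) + 1L,
           test = as.integer(y$partitionings$test[[i]]) + 1L)),
    strata = y$strata, seed = as.integer(y$seed)), class = "split_set")
}

nrow0 <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
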