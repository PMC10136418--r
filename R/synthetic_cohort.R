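#' Generate a synthetic patient cohort with planted endotype structure
#'
#' Draws a complete (no missing cells) mixed-type table from a
#' [cohort_spec()]. Endotype membership is deterministic in count
#' (`round(prevalence * n)`) and randomly placed; members of an endotype
#' have their quantitative features shifted by `D * sd` before clipping to
#' the feature's bounds, and categorical features drawn from the endotype's
#' override probabilities. A seeded subsample of each endotype's members (of
#' size `round(label_fraction * count)`) receives an observed diagnosis
#' label; everyone else is marked [NO_DIAGNOSIS].
#'
#' @param spec a [cohort_spec()]
#' @param seed integer seed; defaults to the spec's own seed. Identical
#'   `(spec, seed)` pairs produce identical cohorts.
#' @return list with elements `table` (a [patient_table()] whose labels are
#'   the observed partial labels), `truth` (character vector of ground-truth
#'   endotype membership, [NO_DIAGNOSIS] for background patients) and
#'   `labels` (the observed partial labels, identical to `table$labels`).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  n <- spec$n_patients
  counts <- endotype_counts(spec)
  if (sum(counts) > n)
    stop("rounded endotype counts (", sum(counts),
         ") exceed n_patients (", n, ")")

  set.seed(as.integer(seed))
  truth <- rep(NO_DIAGNOSIS, n)
  perm <- sample.int(n)
  offset <- 0L
  members <- list()
  for (i in seq_along(spec$endotypes)) {
    nm <- spec$endotypes[[i]]$name
    idx <- perm[seq_len(counts[[i]]) + offset]
    members[[nm]] <- idx
    truth[idx] <- nm
    offset <- offset + counts[[i]]
  }

  data <- list()
  for (f in spec$features) {
    if (f$kind == "quantitative") {
      mu <- rep(f$mean, n)
      for (e in spec$endotypes) {
        d <- e$effect[[f$name]]
        if (!is.null(d)) mu[members[[e$name]]] <- f$mean + d * f$sd
      }
      x <- stats::rnorm(n, mu, f$sd)
      data[[f$name]] <- pmin(pmax(x, f$min), f$max)
    } else {
      x <- sample(f$levels, n, replace = TRUE, prob = f$probs)
      for (e in spec$endotypes) {
        pr <- e$effect[[f$name]]
        if (!is.null(pr)) {
          idx <- members[[e$name]]
          p <- stats::setNames(rep(0, length(f$levels)), f$levels)
          p[names(pr)] <- pr
          x[idx] <- sample(f$levels, length(idx), replace = TRUE, prob = p)
        }
      }
      data[[f$name]] <- factor(x, levels = f$levels)
    }
  }

  labels <- rep(NO_DIAGNOSIS, n)
  for (e in spec$endotypes) {
    idx <- members[[e$name]]
    n_lab <- as.integer(round_half_up(e$label_fraction * length(idx)))
    if (n_lab > 0) {
      lab_idx <- if (n_lab >= length(idx)) idx
                 else idx[sample.int(length(idx), n_lab)]
      labels[lab_idx] <- e$name
    }
  }

  tab <- patient_table(as.data.frame(data, check.names = FALSE),
                       labels = labels)
  list(table = tab, truth = truth, labels = labels)
}

#' Inject missing-completely-at-random cells into a patient table
#'
#' Each patient receives a personal missingness rate drawn from the spec's
#' `missing_patient_rates` distribution; feature cells are then masked
#' independently at that rate. The label vector is never masked.
#'
#' @param table a [patient_table()]
#' @param spec a [cohort_spec()] (only `missing_patient_rates` is used), or
#'   a [missing_rates()] object directly
#' @param seed integer seed
#' @return the table with `NA` in the masked cells
#' @export
inject_missingness <- function(table, spec, seed = 1L) {
  mr <- if (inherits(spec, "missing_rates")) spec
        else spec$missing_patient_rates
  stopifnot(inherits(mr, "missing_rates"))
  n <- n_patients(table)
  p <- length(feature_names(table))
  set.seed(as.integer(seed))
  rates <- draw_missing_rates(mr, n)
  if (any(rates < 0 | rates > 1))
    stop("per-patient missingness rates must lie in [0, 1]")
  mask <- matrix(stats::runif(n * p), n, p) < rates  # recycles by row
  for (j in seq_len(p)) {
    col <- table$data[[j]]
    col[mask[, j]] <- NA
    table$data[[j]] <- col
  }
  table
}

# Table-driven construction of the tinnitus-like cohort specification lives
# in tinnitus_spec.R.
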