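#' Declare a synthetic cohort feature
#'
#' @param name feature identifier (unique within a cohort spec)
#' @param kind `"quantitative"` or `"categorical"`
#' @param mean,sd,min,max baseline distribution for a quantitative feature,
#'   in the feature's native units; values are drawn Gaussian and clipped to
#'   `[min, max]` (use `-Inf`/`Inf` for unbounded features). Requires
#'   `sd > 0` and `min <= mean <= max`.
#' @param levels,probs level names and baseline probabilities for a
#'   categorical feature; `probs` must be non-negative and sum to 1.
#' @return a `feature_spec` object
#' @export
feature_spec <- function(name, kind = c("quantitative", "categorical"),
                         mean = NULL, sd = NULL, min = -Inf, max = Inf,
                         levels = NULL, probs = NULL) {
  kind <- match.arg(kind)
  if (kind == "quantitative") {
    stopifnot(is.numeric(mean), is.numeric(sd))
    if (sd <= 0) stop("feature '", name, "': sd must be > 0")
    if (!(min <= mean && mean <= max))
      stop("feature '", name, "': need min <= mean <= max")
    out <- list(name = name, kind = kind, mean = mean, sd = sd,
                min = min, max = max)
  } else {
    stopifnot(is.character(levels), length(levels) >= 2)
    if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
    probs <- as.numeric(probs)
    if (length(probs) != length(levels) || any(probs < 0) ||
        abs(sum(probs) - 1) > 1e-6)
      stop("feature '", name, "': probs must be >= 0 and sum to 1")
    probs <- probs / sum(probs)
    names(probs) <- levels
    out <- list(name = name, kind = kind, levels = levels, probs = probs)
  }
  structure(out, class = "feature_spec")
}

#' Declare a synthetic endotype
#'
#' An endotype occupies a fixed fraction of the cohort and shifts a subset
#' of features away from their baselines: quantitative entries of `effect`
#' are pooled Cohen's D shifts (the member mean moves by `D * sd`),
#' categorical entries are replacement level-probability vectors.
#'
#' @param name endotype identifier
#' @param prevalence fraction of the cohort in `[0, 1]`
#' @param effect named list: feature name -> numeric D (quantitative) or
#'   named probability vector over the feature's levels (categorical)
#' @param label_fraction fraction of this endotype's members whose ground
#'   truth becomes an observed diagnosis label, in `[0, 1]`
#' @return an `endotype_spec` object
#' @export
endotype_spec <- function(name, prevalence, effect = list(),
                          label_fraction = 1) {
  stopifnot(is.numeric(prevalence), length(prevalence) == 1)
  if (prevalence < 0 || prevalence > 1)
    stop("endotype '", name, "': prevalence must be in [0, 1]")
  if (label_fraction < 0 || label_fraction > 1)
    stop("endotype '", name, "': label_fraction must be in [0, 1]")
  structure(list(name = name, prevalence = prevalence,
                 effect = effect, label_fraction = label_fraction),
            class = "endotype_spec")
}

#' Per-patient missingness rate distribution
#'
#' Describes how each patient's personal missing-cell rate is drawn when
#' missingness is injected (missing completely at random within patient).
#'
#' @param dist `"constant"` or `"uniform"`
#' @param rate the fixed rate for `"constant"`
#' @param min,max the support for `"uniform"`
#' @return a `missing_rates` object
#' @export
missing_rates <- function(dist = c("constant", "uniform"),
                          rate = 0, min = 0, max = 0) {
  dist <- match.arg(dist)
  if (dist == "constant") {
    if (rate < 0 || rate > 1) stop("missingness rate must be in [0, 1]")
    structure(list(dist = dist, rate = rate), class = "missing_rates")
  } else {
    if (min < 0 || max > 1 || min > max)
      stop("uniform missingness bounds must satisfy 0 <= min <= max <= 1")
    structure(list(dist = dist, min = min, max = max),
              class = "missing_rates")
  }
}

draw_missing_rates <- function(mr, n) {
  switch(mr$dist,
         constant = rep(mr$rate, n),
         uniform  = stats::runif(n, mr$min, mr$max))
}

#' Assemble a synthetic cohort specification
#'
#' @param n_patients cohort size (>= 1)
#' @param features list of [feature_spec()] with unique names
#' @param endotypes list of [endotype_spec()]; prevalences must sum to <= 1
#' @param missing_patient_rates a [missing_rates()] distribution used by
#'   [inject_missingness()]
#' @param seed default integer seed for [generate_cohort()]
#' @return a `cohort_spec` object
#' @export
cohort_spec <- function(n_patients, features, endotypes = list(),
                        missing_patient_rates = missing_rates("constant", 0),
                        seed = 1L) {
  spec <- structure(list(n_patients = as.integer(n_patients),
                         features = features, endotypes = endotypes,
                         missing_patient_rates = missing_patient_rates,
                         seed = as.integer(seed)),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks all invariants: positive size, unique feature names, valid
#' baselines, prevalences summing to at most 1, effects referring to
#' declared features/levels.
#'
#' @param spec a [cohort_spec()]
#' @return `spec`, invisibly; stops on the first violation
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_patients < 1) stop("n_patients must be >= 1")
  fnames <- vapply(spec$features, `[[`, character(1), "name")
  if (anyDuplicated(fnames)) stop("feature names must be unique")
  prev <- vapply(spec$endotypes, `[[`, numeric(1), "prevalence")
  if (sum(prev) > 1 + 1e-12) stop("endotype prevalences sum to more than 1")
  fmap <- stats::setNames(spec$features, fnames)
  for (e in spec$endotypes) {
    for (fn in names(e$effect)) {
      if (!fn %in% fnames)
        stop("endotype '", e$name, "' references unknown feature '", fn, "'")
      f <- fmap[[fn]]
      eff <- e$effect[[fn]]
      if (f$kind == "categorical") {
        if (is.null(names(eff)) || !all(names(eff) %in% f$levels) ||
            any(eff < 0) || abs(sum(eff) - 1) > 1e-8)
          stop("endotype '", e$name, "': categorical effect on '", fn,
               "' must be a probability vector over its declared levels")
      } else if (!is.numeric(eff) || length(eff) != 1) {
        stop("endotype '", e$name, "': quantitative effect on '", fn,
             "' must be a single Cohen's D value")
      }
    }
  }
  invisible(spec)
}

# deterministic half-up rounding (round() halves-to-even would make
# endotype counts depend on the binary representation of prevalences)
round_half_up <- function(x) floor(x + 0.5)

#' Endotype member counts implied by a cohort spec
#'
#' Counts are deterministic: `round(prevalence * n_patients)` with halves
#' rounded up, so fixture arithmetic is exact and reproducible.
#'
#' @param spec a [cohort_spec()]
#' @return named integer vector of member counts
#' @export
endotype_counts <- function(spec) {
  prev <- vapply(spec$endotypes, `[[`, numeric(1), "prevalence")
  counts <- as.integer(round_half_up(prev * spec$n_patients))
  names(counts) <- vapply(spec$endotypes, `[[`, character(1), "name")
  counts
}

#' Write / read a cohort spec as YAML
#'
#' Serialized with keys exactly matching the constructor field names, so a
#' spec can be versioned alongside an analysis.
#'
#' @param spec a [cohort_spec()]
#' @param path YAML file path
#' @return `path` (write) or a [cohort_spec()] (read)
#' @export
write_cohort_spec <- function(spec, path) {
  ser <- list(
    n_patients = spec$n_patients,
    seed = spec$seed,
    missing_patient_rates = unclass(spec$missing_patient_rates),
    features = lapply(spec$features, function(f) {
      f <- unclass(f)
      if (f$kind == "categorical") f$probs <- as.numeric(f$probs)
      f
    }),
    endotypes = lapply(spec$endotypes, function(e) {
      e <- unclass(e)
      e$effect <- lapply(e$effect, function(v)
        if (!is.null(names(v))) as.list(v) else v)
      e
    })
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  features <- lapply(y$features, function(f) {
    if (f$kind == "categorical")
      feature_spec(f$name, "categorical", levels = unlist(f$levels),
                   probs = unlist(f$probs))
    else
      feature_spec(f$name, "quantitative", mean = f$mean, sd = f$sd,
                   min = f$min, max = f$max)
  })
  endotypes <- lapply(y$endotypes, function(e) {
    eff <- lapply(e$effect, function(v)
      if (is.list(v)) unlist(v) else v)
    endotype_spec(e$name, e$prevalence, effect = eff,
                  label_fraction = e$label_fraction)
  })
  mr <- y$missing_patient_rates
  mrd <- if (mr$dist == "constant") missing_rates("constant", rate = mr$rate)
         else missing_rates("uniform", min = mr$min, max = mr$max)
  cohort_spec(y$n_patients, features, endotypes,
              missing_patient_rates = mrd, seed = y$seed)
}
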