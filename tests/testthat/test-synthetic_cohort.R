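test_that("endotype counts are deterministic and match the reference prevalences", {
  spec <- tinnitus_cohort_spec()
  counts <- endotype_counts(spec)
  expect_identical(counts[["pulsatile tinnitus"]], 231L)
  expect_identical(unname(counts),
                   c(231L, 38L, 35L, 24L, 14L, 7L))
  expect_identical(sum(counts), 349L)
  # labeled fraction of the cohort, to the printed precision
  expect_equal(round(100 * sum(counts) / spec$n_patients, 2), 12.59)
  co <- generate_cohort(spec, seed = 3)
  expect_identical(sum(co$truth == "pulsatile tinnitus"), 231L)
  expect_identical(sum(co$labels != NO_DIAGNOSIS), 349L)
})

test_that("generation is deterministic under a fixed (spec, seed)", {
  spec <- tinnitus_cohort_spec(n_patients = 200)
  a <- generate_cohort(spec, seed = 7)
  b <- generate_cohort(spec, seed = 7)
  expect_identical(a$table$data, b$table$data)
  expect_identical(a$truth, b$truth)
  expect_identical(a$labels, b$labels)
  c_ <- generate_cohort(spec, seed = 8)
  expect_false(identical(a$table$data, c_$table$data))
})

test_that("label_fraction 0 leaves the whole cohort undiagnosed", {
  spec <- tinnitus_cohort_spec(n_patients = 300)
  spec$endotypes <- lapply(spec$endotypes, function(e) {
    e$label_fraction <- 0; e
  })
  co <- generate_cohort(spec, seed = 1)
  expect_true(all(co$labels == NO_DIAGNOSIS))
  expect_gt(sum(co$truth != NO_DIAGNOSIS), 0)
})

test_that("invalid specs are rejected", {
  f <- feature_spec("x", "quantitative", mean = 0, sd = 1)
  expect_error(cohort_spec(10, list(f),
                           list(endotype_spec("a", 0.7),
                                endotype_spec("b", 0.6))),
               "sum to more than 1")
  expect_error(feature_spec("x", "quantitative", mean = 0, sd = 0),
               "sd must be")
  expect_error(feature_spec("x", "quantitative", mean = 5, sd = 1,
                            min = 0, max = 2), "min <= mean <= max")
  expect_error(feature_spec("x", "categorical", levels = c("a", "b"),
                            probs = c(0.8, 0.8)), "sum to 1")
  expect_error(cohort_spec(10, list(f, f)), "unique")
  # rounded counts exceeding n
  sp <- cohort_spec(3, list(f), list(endotype_spec("a", 0.5),
                                     endotype_spec("b", 0.5)))
  expect_error(generate_cohort(sp, seed = 1), "exceed n_patients")
})

test_that("planted quantitative effects are recovered from the generated table", {
  # unbounded features so clipping cannot attenuate the planted shift
  feats <- list(
    feature_spec("f1", "quantitative", mean = 10, sd = 4),
    feature_spec("f2", "quantitative", mean = 0, sd = 1),
    feature_spec("g", "categorical", levels = c("a", "b"),
                 probs = c(0.5, 0.5)))
  planted <- c(f1 = 1.0, f2 = -1.6)
  spec <- cohort_spec(5000, feats,
                      list(endotype_spec("e", 0.3,
                                         effect = as.list(planted))))
  co <- generate_cohort(spec, seed = 11)
  for (nm in names(planted)) {
    x <- co$table$data[[nm]]
    inside <- co$truth == "e"
    n_in <- sum(inside); n_out <- sum(!inside)
    sp <- sqrt(((n_in - 1) * var(x[inside]) + (n_out - 1) * var(x[!inside])) /
                 (n_in + n_out - 2))
    d_hat <- (mean(x[inside]) - mean(x[!inside])) / sp
    se <- sqrt(1 / n_in + 1 / n_out)  # large-sample SE of Cohen's D
    expect_lt(abs(d_hat - planted[[nm]]), max(0.1, 3 * se))
  }
})

test_that("missingness injection follows the per-patient rate distribution", {
  spec <- tinnitus_cohort_spec(n_patients = 100)
  co <- generate_cohort(spec, seed = 2)

  zero <- spec; zero$missing_patient_rates <- missing_rates("constant", 0)
  expect_identical(inject_missingness(co$table, zero, seed = 5)$data,
                   co$table$data)

  full <- spec; full$missing_patient_rates <- missing_rates("constant", 1)
  masked <- inject_missingness(co$table, full, seed = 5)
  expect_true(all(missing_mask(masked)))
  expect_identical(masked$labels, co$table$labels)  # labels never masked

  spec2 <- tinnitus_cohort_spec(n_patients = 2000)
  co2 <- generate_cohort(spec2, seed = 3)
  spec2$missing_patient_rates <- missing_rates("uniform", min = 0, max = 0.5)
  m <- inject_missingness(co2$table, spec2, seed = 9)
  expect_lt(abs(mean(missing_mask(m)) - 0.25), 0.02)
})

test_that("cohort specs round-trip through YAML and tables through CSV", {
  spec <- tinnitus_cohort_spec(n_patients = 50)
  path <- tempfile(fileext = ".yaml")
  write_cohort_spec(spec, path)
  spec2 <- read_cohort_spec(path)
  expect_equal(endotype_counts(spec2), endotype_counts(spec))
  expect_equal(length(spec2$features), length(spec$features))
  co <- generate_cohort(spec2, seed = 4)
  co_ref <- generate_cohort(spec, seed = 4)
  expect_equal(co$table$data, co_ref$table$data, tolerance = 1e-12)

  tab <- inject_missingness(co$table, spec, seed = 6)
  csv <- tempfile(fileext = ".csv")
  write_patient_table(tab, csv)
  back <- read_patient_table(csv)
  expect_equal(back$labels, tab$labels)
  expect_equal(missing_mask(back), missing_mask(tab))
  expect_equal(back$data$age, tab$data$age, tolerance = 1e-12)
  expect_identical(levels(back$data$side), levels(tab$data$side))
})

test_that("baseline questionnaire scales keep their reference moments", {
  spec <- tinnitus_cohort_spec(n_patients = 5000)
  co <- generate_cohort(spec, seed = 21)
  # baselines are checked on the background (non-endotype) patients, since
  # planted endotype shifts move the marginal mean by construction
  bg <- co$truth == NO_DIAGNOSIS
  expect_lt(abs(mean(co$table$data$thi[bg]) - 50.98), 1)
  expect_lt(abs(mean(co$table$data$age[bg]) - 51.3), 1)
  # bounded scales stay in range after shifting and clipping
  expect_true(all(co$table$data$vas_vertigo >= 0 &
                    co$table$data$vas_vertigo <= 10))
})
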