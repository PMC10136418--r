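#' Reference synthetic tinnitus cohort specification
#'
#' A ready-made [cohort_spec()] emulating a large tinnitus case-history
#' database: 18 quantitative questionnaire features (age, THI, VAS scales,
#' HAD, ISI, Epworth, ...) with published-scale means/SDs and bounds, 24
#' categorical features with realistic level frequencies, and six diagnosed
#' endotypes (pulsatile tinnitus 8.33%, otosclerosis 1.37%, Meniere's
#' disease 1.26%, neurinoma 0.87%, petrous bone fracture 0.51%, Eustachian
#' tube dysfunction 0.25% - 12.59% of the cohort labeled in total). Each
#' endotype plants a clinically shaped signature: categorical probability
#' overrides (e.g. the pulsatile endotype almost always answers yes to "is
#' the tinnitus pulsatile?") plus quantitative shifts with |D| between 1.5
#' and 3.
#'
#' Per-patient missingness (for [inject_missingness()]) defaults to
#' Uniform(0, 8/15), which emulates a raw, pre-filtering database in which
#' about a quarter of patients exceed the 40% patient-filter threshold.
#'
#' @param n_patients cohort size; 2772 by default
#' @param seed default generation seed carried inside the spec
#' @return a [cohort_spec()]
#' @export
tinnitus_cohort_spec <- function(n_patients = 2772, seed = 20230328L) {
  q <- function(name, mean, sd, min, max)
    feature_spec(name, "quantitative", mean = mean, sd = sd,
                 min = min, max = max)
  cat2 <- function(name, yes, no)
    feature_spec(name, "categorical", levels = c("yes", "no"),
                 probs = c(yes, no) / (yes + no))
  catn <- function(name, levels, counts)
    feature_spec(name, "categorical", levels = levels,
                 probs = counts / sum(counts))

  features <- list(
    q("age", 51.3, 14.74, 18, 95),
    q("thi", 50.98, 23.83, 0, 100),
    q("tinnitus_duration", 67.79, 93.12, 0, 852),
    q("pct_time_present", 66.34, 28.19, 0, 100),
    q("vas_annoyance", 6.89, 2.17, 0, 10),
    q("vas_anxiety", 4.89, 3.25, 0, 10),
    q("vas_sleep_quality", 5.25, 3.35, 0, 10),
    q("vas_hyperacusis", 5.05, 3.41, 0, 10),
    q("vas_vertigo", 2.36, 2.94, 0, 10),
    q("vas_headache", 2.16, 3.23, 0, 10),
    q("vas_jaw_pain", 1.90, 2.79, 0, 10),
    q("vas_cervical_pain", 2.63, 3.39, 0, 10),
    q("khalfa_hyperacusis", 19.72, 9.73, 0, 42),
    q("had_anxiety", 9.18, 4.24, 0, 21),
    q("had_depression", 6.47, 4.60, 0, 21),
    q("isi", 12.39, 6.62, 0, 28),
    q("epworth", 7.62, 4.70, 0, 24),
    q("sleep_latency", 35.72, 27.23, 0, 121),
    catn("gender", c("female", "male"), c(1491, 1226)),
    catn("apparition", c("brutal", "progressive"), c(1665, 1099)),
    catn("side", c("left", "bilateral", "right"), c(1015, 910, 760)),
    catn("lateralisation", c("bilateral", "partial", "lateral"),
         c(910, 743, 1032)),
    catn("intensity", c("low", "medium", "elevated"), c(1282, 990, 500)),
    cat2("acoustic_trauma", 460, 2304),
    cat2("pulsatile", 231, 2533),
    cat2("narrow_band", 283, 2481),
    cat2("somato_modulation", 446, 2318),
    cat2("jaw_modulation", 317, 2447),
    cat2("neck_modulation", 256, 2508),
    cat2("headaches", 826, 1938),
    cat2("cervical_pain", 1198, 1566),
    catn("trouble_falling_asleep", c("yes", "sometimes", "no"),
         c(972, 505, 1134)),
    catn("nocturnal_awakenings", c("yes", "sometimes", "no"),
         c(425, 530, 1644)),
    catn("tired_when_awake", c("yes", "sometimes", "no"),
         c(653, 574, 1360)),
    cat2("snoring", 1152, 1438),
    catn("sleep_apnea", c("yes", "probably", "no"), c(217, 238, 2102)),
    cat2("normal_hearing", 337, 2427),
    cat2("sensorineural_hl", 1563, 656),
    cat2("transmissional_hl", 197, 2022),
    cat2("notch_hl", 251, 1968),
    cat2("high_freq_hl", 146, 2073),
    cat2("cophosis", 38, 2181)
  )

  # Each endotype plants a syndrome-wide signature (~9-11 affected
  # features), mirroring the breadth of per-cluster differentiation that
  # profiled real clusterings exhibit; quantitative shifts all have
  # |D| in [1.5, 3].
  yn <- function(yes) c(yes = yes, no = 1 - yes)
  endotypes <- list(
    endotype_spec("pulsatile tinnitus", 0.0833, effect = list(
      pulsatile = yn(0.97),
      gender = c(female = 0.75, male = 0.25),
      lateralisation = c(bilateral = 0.08, partial = 0.22, lateral = 0.70),
      normal_hearing = yn(0.55),
      sensorineural_hl = yn(0.25),
      age = -1.5, tinnitus_duration = -1.5, sleep_latency = 1.5,
      vas_anxiety = 1.5
    )),
    endotype_spec("otosclerosis", 0.0137, effect = list(
      transmissional_hl = yn(0.95),
      apparition = c(brutal = 0.12, progressive = 0.88),
      gender = c(female = 0.78, male = 0.22),
      sensorineural_hl = yn(0.2),
      thi = 1.8, vas_vertigo = 1.5, isi = 1.6, vas_sleep_quality = 1.5,
      age = -1.6, vas_annoyance = 1.5
    )),
    endotype_spec("meniere disease", 0.0126, effect = list(
      sensorineural_hl = yn(0.92),
      side = c(left = 0.55, bilateral = 0.10, right = 0.35),
      nocturnal_awakenings = c(yes = 0.60, sometimes = 0.25, no = 0.15),
      vas_vertigo = 2.5, isi = 1.6, epworth = 1.5, had_anxiety = 1.8,
      vas_annoyance = 1.6, pct_time_present = 1.5
    )),
    endotype_spec("neurinoma", 0.0087, effect = list(
      cophosis = yn(0.85),
      lateralisation = c(bilateral = 0.04, partial = 0.11, lateral = 0.85),
      sensorineural_hl = yn(0.3),
      intensity = c(low = 0.10, medium = 0.30, elevated = 0.60),
      khalfa_hyperacusis = 2.0, vas_hyperacusis = 1.8, age = 1.5,
      thi = 1.6, vas_vertigo = 1.6
    )),
    endotype_spec("petrous bone fracture", 0.0051, effect = list(
      apparition = c(brutal = 0.92, progressive = 0.08),
      headaches = yn(0.85),
      cervical_pain = yn(0.80),
      vas_headache = 2.5, vas_cervical_pain = 2.2, vas_jaw_pain = 1.8,
      had_anxiety = 1.8, had_depression = 1.6, vas_vertigo = 1.8,
      age = -1.5
    )),
    endotype_spec("eustachian tube dysfunction", 0.0025, effect = list(
      narrow_band = yn(0.85),
      intensity = c(low = 0.75, medium = 0.18, elevated = 0.07),
      normal_hearing = yn(0.70),
      snoring = yn(0.75),
      epworth = 1.8, pct_time_present = -1.8, vas_annoyance = -1.5,
      thi = -1.5, khalfa_hyperacusis = -1.5
    ))
  )

  cohort_spec(n_patients, features, endotypes,
              missing_patient_rates = missing_rates("uniform", min = 0,
                                                    max = 8 / 15),
              seed = seed)
}
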