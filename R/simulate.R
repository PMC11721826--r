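# Seeded synthetic claims generator. Emulates the structure of a national
# claims extract: per-patient visit streams of ICD-10 codes over a fixed
# study period, a pediatric age distribution, a rare index disease with male
# excess, and configurable marginal code prevalences with planted
# case-vs-control odds ratios whose recovery validates the whole pipeline.

#' Default ICD-10 code catalog for the synthetic generator
#'
#' A catalog of common pediatric three-character ICD-10 categories with
#' plausible childhood period prevalences (probability that a child has the
#' condition at some point during follow-up). Mirrors the mix seen in
#' pediatric claims: frequent respiratory/ENT/skin codes, uncommon
#' musculoskeletal and injury codes, rare congenital codes.
#'
#' @return Tibble with columns `icd10_code` and `baseline_prevalence`.
#' @export
default_code_catalog <- function() {
  tibble::tribble(
    ~icd10_code, ~baseline_prevalence,
    "J06", 0.60,  # acute upper respiratory infection
    "A09", 0.30,  # infectious gastroenteritis
    "J20", 0.30,  # acute bronchitis
    "J45", 0.30,  # asthma
    "H66", 0.25,  # otitis media
    "L20", 0.20,  # atopic dermatitis
    "L01", 0.15,  # impetigo
    "H60", 0.12,  # otitis externa
    "L24", 0.10,  # irritant contact dermatitis
    "H16", 0.08,  # keratitis
    "J41", 0.05,  # chronic bronchitis
    "S80", 0.05,  # superficial injury, lower leg
    "S83", 0.04,  # knee dislocation/sprain
    "S50", 0.03,  # superficial injury, forearm
    "S33", 0.03,  # lumbar/pelvic sprain
    "M67", 0.03,  # disorders of synovium and tendon
    "D64", 0.02,  # other anemias
    "M65", 0.02,  # synovitis and tenosynovitis
    "M62", 0.02,  # other disorders of muscle
    "M54", 0.02,  # dorsalgia
    "S70", 0.02,  # superficial injury, hip and thigh
    "S73", 0.02,  # hip dislocation/sprain
    "S30", 0.02,  # superficial injury, abdomen/lower back/pelvis
    "T00", 0.02,  # superficial injuries, multiple regions
    "M41", 0.010, # scoliosis
    "M00", 0.005, # pyogenic arthritis
    "Q65", 0.005, # congenital deformities of hip
    "Q66", 0.005  # congenital deformities of feet
  )
}

#' Index disease settings for the synthetic generator
#'
#' @param codes Full ICD-10 codes emitted for the index disease.
#' @param incidence_female_per_100k Annual incidence among girls per 100,000.
#' @param male_case_multiplier Male:female incidence rate ratio.
#' @param followup_rate Mean index-coded follow-up visits per year after the
#'   first diagnosis (exercises washout logic downstream).
#' @return A list with the four components, validated.
#' @export
index_disease_spec <- function(codes = c("M91.1", "M91.8", "M91.9"),
                               incidence_female_per_100k = 3.4,
                               male_case_multiplier = 9.3 / 3.4,
                               followup_rate = 0.5) {
  check_that(length(codes) >= 1 && all(is_valid_icd10(codes)),
             "index_disease$codes", "must be valid ICD-10 codes")
  check_that(incidence_female_per_100k > 0, "index_disease$incidence_female_per_100k",
             "must be > 0")
  check_that(male_case_multiplier > 0, "index_disease$male_case_multiplier",
             "must be > 0")
  check_that(followup_rate >= 0, "index_disease$followup_rate", "must be >= 0")
  list(codes = codes,
       incidence_female_per_100k = incidence_female_per_100k,
       male_case_multiplier = male_case_multiplier,
       followup_rate = followup_rate)
}

#' Configuration of the synthetic claims generator
#'
#' All stochastic structure of a generated dataset is fixed here; the same
#' configuration (including `seed`) always produces an identical dataset.
#'
#' @param n_patients Number of patients.
#' @param study_start,study_end First and last calendar day of the study
#'   period; no claim falls outside it.
#' @param male_fraction Probability that a patient is male.
#' @param age_range Integer age (years) at `study_start`, drawn uniformly;
#'   negative values mean the patient is born after the study starts, and
#'   observation then begins at birth.
#' @param visit_rate Mean background (general-examination, code `Z00`) visits
#'   per patient-year (Poisson).
#' @param condition_visit_rate Mean coded visits per condition-year: each
#'   condition a patient carries generates its own Poisson visit stream, so a
#'   carried condition is almost surely coded at least once in a multi-year
#'   record window.
#' @param code_catalog Data frame `icd10_code`, `baseline_prevalence`: the
#'   per-patient probability of carrying each condition.
#' @param index_disease See [index_disease_spec()].
#' @param planted_effects Optional data frame `code`, `odds_ratio`: for index
#'   cases, the carriage probability of `code` is tilted so the population
#'   case-vs-control odds ratio of carriage equals `odds_ratio`.
#' @param pairwise_effects Optional data frame `code_a`, `code_b`,
#'   `odds_ratio`: the two carriage indicators are drawn jointly with the
#'   given odds ratio (Plackett construction), identically in cases and
#'   controls. A code may appear in at most one pair and not also in
#'   `planted_effects`.
#' @param missingness_fraction Probability that a patient's demographic
#'   fields are missing (such patients are flagged incomplete downstream).
#' @param subcode_fraction Fraction of emitted claims given a random fourth
#'   digit (e.g. `"J45.0"`), exercising three-character truncation.
#' @param seed Integer seed; same config + seed gives a byte-identical
#'   dataset.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 500, seed = 1)
#' cs <- generate_claims(cfg)
#' cs
sim_config <- function(n_patients = 20000,
                       study_start = as.Date("2002-01-01"),
                       study_end = as.Date("2015-12-31"),
                       male_fraction = 0.5,
                       age_range = c(-8L, 12L),
                       visit_rate = 2,
                       condition_visit_rate = 1.5,
                       code_catalog = default_code_catalog(),
                       index_disease = index_disease_spec(),
                       planted_effects = NULL,
                       pairwise_effects = NULL,
                       missingness_fraction = 0.05,
                       subcode_fraction = 0.3,
                       seed = 1L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  check_that(is.numeric(n_patients) && n_patients >= 1, "n_patients",
             "must be a positive count")
  check_that(!is.na(study_start) && !is.na(study_end) && study_start < study_end,
             "study_start/study_end", "study_start must precede study_end")
  check_that(male_fraction >= 0 && male_fraction <= 1, "male_fraction",
             "must be a probability in [0, 1]")
  check_that(length(age_range) == 2 && age_range[1] <= age_range[2],
             "age_range", "must be increasing [min, max]")
  y0 <- as.integer(format(study_start, "%Y"))
  y1 <- as.integer(format(study_end, "%Y"))
  check_that(y0 - age_range[1] <= y1, "age_range",
             "minimum age implies births after the study ends")
  check_that(visit_rate >= 0, "visit_rate", "must be >= 0")
  check_that(condition_visit_rate >= 0, "condition_visit_rate", "must be >= 0")
  code_catalog <- tibble::as_tibble(code_catalog)
  check_that(all(c("icd10_code", "baseline_prevalence") %in% names(code_catalog)),
             "code_catalog", "needs columns icd10_code, baseline_prevalence")
  check_that(all(is_valid_icd10(code_catalog$icd10_code)), "code_catalog",
             "contains invalid ICD-10 codes")
  check_that(!anyDuplicated(code_catalog$icd10_code), "code_catalog",
             "duplicate codes")
  check_that(all(code_catalog$baseline_prevalence >= 0 &
                 code_catalog$baseline_prevalence <= 1), "code_catalog",
             "prevalences must be probabilities in [0, 1]")
  if (!is.null(planted_effects)) {
    planted_effects <- tibble::as_tibble(planted_effects)
    check_that(all(c("code", "odds_ratio") %in% names(planted_effects)),
               "planted_effects", "needs columns code, odds_ratio")
    check_that(all(planted_effects$code %in% code_catalog$icd10_code),
               "planted_effects", "codes must be in code_catalog")
    check_that(all(planted_effects$odds_ratio > 0), "planted_effects",
               "odds ratios must be > 0")
    check_that(!anyDuplicated(planted_effects$code), "planted_effects",
               "duplicate codes")
  }
  if (!is.null(pairwise_effects)) {
    pairwise_effects <- tibble::as_tibble(pairwise_effects)
    check_that(all(c("code_a", "code_b", "odds_ratio") %in% names(pairwise_effects)),
               "pairwise_effects", "needs columns code_a, code_b, odds_ratio")
    pw <- c(pairwise_effects$code_a, pairwise_effects$code_b)
    check_that(all(pw %in% code_catalog$icd10_code), "pairwise_effects",
               "codes must be in code_catalog")
    check_that(!anyDuplicated(pw), "pairwise_effects",
               "a code may appear in at most one pair")
    check_that(all(pairwise_effects$odds_ratio > 0), "pairwise_effects",
               "odds ratios must be > 0")
    if (!is.null(planted_effects)) {
      check_that(length(intersect(pw, planted_effects$code)) == 0,
                 "pairwise_effects",
                 "codes overlap planted_effects")
    }
  }
  check_that(missingness_fraction >= 0 && missingness_fraction <= 1,
             "missingness_fraction", "must be a probability in [0, 1]")
  check_that(subcode_fraction >= 0 && subcode_fraction <= 1,
             "subcode_fraction", "must be a probability in [0, 1]")
  check_that(is.numeric(seed) && length(seed) == 1 && !is.na(seed),
             "seed", "must be a single integer")
  structure(list(
    n_patients = as.integer(n_patients),
    study_start = study_start, study_end = study_end,
    male_fraction = male_fraction,
    age_range = as.integer(age_range),
    visit_rate = visit_rate,
    condition_visit_rate = condition_visit_rate,
    code_catalog = code_catalog,
    index_disease = index_disease,
    planted_effects = planted_effects,
    pairwise_effects = pairwise_effects,
    missingness_fraction = missingness_fraction,
    subcode_fraction = subcode_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Tilted carriage probability giving the target case-vs-control odds ratio:
# with control odds o = p0/(1-p0), case probability is OR*o / (1 + OR*o).
tilt_prevalence <- function(p0, or) {
  o <- or * p0 / (1 - p0)
  o / (1 + o)
}

# Plackett joint-success probability p11 for marginals pa, pb and odds ratio
# psi: the unique root in [max(0, pa+pb-1), min(pa, pb)].
plackett_p11 <- function(pa, pb, psi) {
  if (abs(psi - 1) < 1e-12) return(pa * pb)
  s <- 1 + (pa + pb) * (psi - 1)
  (s - sqrt(s^2 - 4 * psi * (psi - 1) * pa * pb)) / (2 * (psi - 1))
}

#' Generate a synthetic claims dataset
#'
#' Draws demographics, index-disease onset, latent condition carriage and
#' visit streams per [sim_config()]. Carriage (presence/absence), not visit
#' counts, carries the planted odds ratios; each carried condition emits its
#' own Poisson visit stream so that downstream presence ascertainment over a
#' multi-year pre-index window recovers carriage with near-certainty. Index
#' codes are emitted at the first-diagnosis date and may recur later as
#' follow-up visits, exercising washout logic.
#'
#' @param config A [sim_config()].
#' @return A [claims_set()] with attributes `truth` (tibble: `patient_id`,
#'   `is_case`, `diagnosis_date`, plus the true demographics even where the
#'   emitted ones are missing) and `config`.
#' @export
generate_claims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_patients
  start <- config$study_start
  end <- config$study_end
  y0 <- as.integer(format(start, "%Y"))

  sex <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")
  age0 <- config$age_range[1] +
    floor(stats::runif(n) * (config$age_range[2] - config$age_range[1] + 1L))
  birth_year <- y0 - as.integer(age0)
  birth_date <- as.Date(paste0(birth_year, "-01-01"))
  obs_start <- pmax(start, birth_date)
  span <- as.integer(end - obs_start) + 1L
  years_obs <- span / 365.25

  # index disease onset
  rate <- config$index_disease$incidence_female_per_100k / 1e5
  rate <- rate * ifelse(sex == "M", config$index_disease$male_case_multiplier, 1)
  p_case <- pmin(1, rate * years_obs)
  is_case <- stats::runif(n) < p_case
  diagnosis_date <- as.Date(rep(NA, n))
  n_case <- sum(is_case)
  if (n_case) {
    diagnosis_date[is_case] <- obs_start[is_case] +
      floor(stats::runif(n_case) * span[is_case])
  }

  # latent condition carriage
  cat_codes <- config$code_catalog$icd10_code
  J <- length(cat_codes)
  p0 <- config$code_catalog$baseline_prevalence
  has <- matrix(FALSE, n, J)
  planted <- config$planted_effects
  for (j in seq_len(J)) {
    pj <- rep(p0[j], n)
    if (!is.null(planted) && cat_codes[j] %in% planted$code) {
      or <- planted$odds_ratio[match(cat_codes[j], planted$code)]
      pj[is_case] <- tilt_prevalence(p0[j], or)
    }
    has[, j] <- stats::runif(n) < pj
  }
  if (!is.null(config$pairwise_effects)) {
    pw <- config$pairwise_effects
    for (k in seq_len(nrow(pw))) {
      ja <- match(pw$code_a[k], cat_codes)
      jb <- match(pw$code_b[k], cat_codes)
      p11 <- plackett_p11(p0[ja], p0[jb], pw$odds_ratio[k])
      ha <- stats::runif(n) < p0[ja]
      pb_cond <- ifelse(ha, p11 / p0[ja], (p0[jb] - p11) / (1 - p0[ja]))
      has[, ja] <- ha
      has[, jb] <- stats::runif(n) < pb_cond
    }
  }

  patient_id <- sprintf("P%07d", seq_len(n))

  # background general-examination visits
  k0 <- stats::rpois(n, config$visit_rate * years_obs)
  i0 <- rep.int(seq_len(n), k0)
  bg <- tibble::tibble(
    patient_id = patient_id[i0],
    visit_date = obs_start[i0] + floor(stats::runif(length(i0)) * span[i0]),
    icd10_code = "Z00"
  )

  # per-condition visit streams
  w <- which(has)
  ci <- ((w - 1L) %% n) + 1L
  cj <- ((w - 1L) %/% n) + 1L
  kc <- stats::rpois(length(ci), config$condition_visit_rate * years_obs[ci])
  ic <- rep.int(ci, kc)
  jc <- rep.int(cj, kc)
  code <- cat_codes[jc]
  sub <- stats::runif(length(code)) < config$subcode_fraction
  # only three-character catalog codes can take a random fourth digit
  sub <- sub & nchar(code) == 3
  if (any(sub)) {
    code[sub] <- paste0(code[sub], ".",
                        floor(stats::runif(sum(sub)) * 10))
  }
  cond <- tibble::tibble(
    patient_id = patient_id[ic],
    visit_date = obs_start[ic] + floor(stats::runif(length(ic)) * span[ic]),
    icd10_code = code
  )

  # index-disease visits: one at diagnosis, Poisson follow-ups after
  idx <- NULL
  if (n_case) {
    wcase <- which(is_case)
    first <- tibble::tibble(
      patient_id = patient_id[wcase],
      visit_date = diagnosis_date[wcase],
      icd10_code = sample(config$index_disease$codes, n_case, replace = TRUE)
    )
    after <- as.integer(end - diagnosis_date[wcase])
    kf <- stats::rpois(n_case, config$index_disease$followup_rate * after / 365.25)
    fi <- rep.int(seq_len(n_case), kf)
    fu <- tibble::tibble(
      patient_id = patient_id[wcase][fi],
      visit_date = diagnosis_date[wcase][fi] + 1L +
        floor(stats::runif(length(fi)) * pmax(after[fi] - 1L, 0L)),
      icd10_code = sample(config$index_disease$codes, length(fi), replace = TRUE)
    )
    idx <- dplyr::bind_rows(first, fu)
  }

  claims <- dplyr::bind_rows(bg, cond, idx)

  miss <- stats::runif(n) < config$missingness_fraction
  patients <- tibble::tibble(
    patient_id = patient_id,
    sex = ifelse(miss, NA_character_, sex),
    birth_year = ifelse(miss, NA_integer_, birth_year)
  )

  out <- claims_set(patients, claims)
  attr(out, "truth") <- tibble::tibble(
    patient_id = patient_id, is_case = is_case,
    diagnosis_date = diagnosis_date, sex = sex, birth_year = birth_year
  )
  attr(out, "config") <- config
  out
}

#' Read a generator configuration from YAML or JSON
#'
#' The file holds a mapping mirroring [sim_config()]'s arguments; nested
#' mappings `code_catalog` (list of `icd10_code`/`baseline_prevalence`
#' records), `index_disease` ([index_disease_spec()] arguments),
#' `planted_effects` and `pairwise_effects` are converted accordingly.
#' Unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  check_that(length(unknown) == 0, "config",
             paste("unknown field(s):", paste(unknown, collapse = ", ")))
  as_records <- function(x) {
    if (is.data.frame(x)) x else dplyr::bind_rows(x)
  }
  if (!is.null(raw$code_catalog)) raw$code_catalog <- as_records(raw$code_catalog)
  if (!is.null(raw$planted_effects)) {
    raw$planted_effects <- as_records(raw$planted_effects)
  }
  if (!is.null(raw$pairwise_effects)) {
    raw$pairwise_effects <- as_records(raw$pairwise_effects)
  }
  if (!is.null(raw$index_disease)) {
    raw$index_disease <- do.call(index_disease_spec, raw$index_disease)
  }
  if (!is.null(raw$age_range)) raw$age_range <- as.integer(raw$age_range)
  do.call(sim_config, raw)
}

#' Packaged demonstration configuration
#'
#' A generator configuration at validation scale: 20,000 patients over an
#' eight-year study period, a compact catalog of five null pediatric codes
#' and three comorbidities with planted case-control odds ratios of 2, 5 and
#' 10, and index-disease incidence calibrated (analytically, from the
#' washout/age retention fraction of this design) so the expected incident
#' case count is about 167 — the case-group size of the published study this
#' design mirrors, at a 1:12 scale of its source database. The male:female
#' incidence ratio is the published 9.3:3.4.
#'
#' @param seed Integer seed.
#' @param n_patients Number of patients.
#' @return A [sim_config()].
#' @export
demo_config <- function(seed = 1L, n_patients = 20000) {
  sim_config(
    n_patients = n_patients,
    study_start = as.Date("2002-01-01"),
    study_end = as.Date("2009-12-31"),
    age_range = c(-7L, 12L),
    visit_rate = 1,
    condition_visit_rate = 1.5,
    code_catalog = tibble::tribble(
      ~icd10_code, ~baseline_prevalence,
      "J06", 0.35,
      "A09", 0.20,
      "H66", 0.15,
      "L20", 0.10,
      "S83", 0.04,
      "D64", 0.05,
      "M67", 0.05,
      "Q65", 0.03
    ),
    index_disease = index_disease_spec(incidence_female_per_100k = 143,
                                       male_case_multiplier = 9.3 / 3.4),
    planted_effects = data.frame(code = c("D64", "M67", "Q65"),
                                 odds_ratio = c(2, 5, 10)),
    missingness_fraction = 0.02,
    seed = seed
  )
}

#' Cohort definition matching [demo_config()]
#'
#' Same index codes, age limit and washout as the default [cohort_spec()],
#' with observation ending at the demo study end.
#'
#' @return A [cohort_spec()].
#' @export
demo_cohort_spec <- function() {
  cohort_spec(observation_end = as.Date("2009-12-31"))
}

#' Simulate a case-control presence matrix directly
#'
#' Draws per-patient cluster-presence indicators for a fixed case-control
#' cohort, bypassing claims generation. Useful for calibration and power
#' studies of the association stage on its own input contract: under
#' `case_odds_ratio = 1` every cluster is null, so the per-cluster
#' significance rate of [screen_clusters()] estimates its type-I error.
#'
#' @param n_cases,n_controls Cohort arm sizes.
#' @param prevalence Named numeric vector of control-arm cluster prevalences
#'   (names are three-character cluster codes).
#' @param case_odds_ratio Case-vs-control odds ratio per cluster (recycled).
#' @param seed Integer seed.
#' @return A `presence_matrix` (see [presence_matrix()]).
#' @export
simulate_presence <- function(n_cases = 167, n_controls = 501, prevalence,
                              case_odds_ratio = 1, seed = 1L) {
  check_that(!is.null(names(prevalence)) && all(nzchar(names(prevalence))),
             "prevalence", "must be a named vector")
  check_that(all(prevalence >= 0 & prevalence <= 1), "prevalence",
             "must be probabilities in [0, 1]")
  check_that(all(case_odds_ratio > 0), "case_odds_ratio", "must be > 0")
  withr::local_seed(seed)
  or <- rep_len(case_odds_ratio, length(prevalence))
  p_case <- tilt_prevalence(prevalence, or)
  ind_case <- matrix(stats::runif(n_cases * length(prevalence)), n_cases) <
    matrix(p_case, n_cases, length(prevalence), byrow = TRUE)
  ind_ctrl <- matrix(stats::runif(n_controls * length(prevalence)), n_controls) <
    matrix(prevalence, n_controls, length(prevalence), byrow = TRUE)
  ind <- rbind(ind_case, ind_ctrl)
  colnames(ind) <- names(prevalence)
  rownames(ind) <- c(sprintf("case%04d", seq_len(n_cases)),
                     sprintf("ctrl%04d", seq_len(n_controls)))
  new_presence_matrix(ind, c(rep(TRUE, n_cases), rep(FALSE, n_controls)))
}
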