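# Incident-case cohort construction: washout, age limit, completeness,
# pre-diagnosis record extraction.

#' Cohort definition for the index disease
#'
#' @param index_codes ICD-10 code prefixes identifying the index disease. A
#'   claim matches when its code equals a prefix or extends it (so `"M91"`
#'   matches every `M91.x` only if explicitly configured; the default uses
#'   the three four-character juvenile hip osteochondrosis codes verbatim).
#' @param max_age_years Maximum age (whole years) at first index-coded visit.
#' @param washout_start,washout_end Calendar window used only to exclude
#'   prevalent patients: anyone index-coded inside it is never a case.
#' @param observation_end Last day of observation (used downstream for
#'   control pseudo-index feasibility).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(index_codes = c("M91.1", "M91.8", "M91.9"),
                        max_age_years = 12L,
                        washout_start = as.Date("2002-01-01"),
                        washout_end = as.Date("2004-12-31"),
                        observation_end = as.Date("2015-12-31")) {
  washout_start <- as.Date(washout_start)
  washout_end <- as.Date(washout_end)
  observation_end <- as.Date(observation_end)
  check_that(length(index_codes) >= 1 && all(is_valid_icd10(index_codes)),
             "index_codes", "must be a nonempty set of valid ICD-10 codes")
  check_that(max_age_years > 0, "max_age_years", "must be > 0")
  check_that(washout_start <= washout_end, "washout_start/washout_end",
             "washout_start must not exceed washout_end")
  check_that(washout_end < observation_end, "observation_end",
             "must fall after the washout window")
  structure(list(index_codes = index_codes,
                 max_age_years = as.integer(max_age_years),
                 washout_start = washout_start,
                 washout_end = washout_end,
                 observation_end = observation_end),
            class = "cohort_spec")
}

#' Match claims codes against index-disease prefixes
#'
#' Prefix semantics: a code matches when it equals a prefix exactly or
#' refines it with a dot subdivision (`"M91.1"` matches prefix `"M91.1"` and
#' `"M91"`, not `"M91.8"`).
#'
#' @param codes Character vector of claim codes.
#' @param index_codes Character vector of prefixes.
#' @return Logical vector along `codes`.
#' @export
match_index_codes <- function(codes, index_codes) {
  hit <- rep(FALSE, length(codes))
  for (pfx in index_codes) {
    hit <- hit | codes == pfx | startsWith(codes, paste0(pfx, "."))
  }
  hit
}

#' Identify incident index-disease cases
#'
#' A patient is an incident case iff (a) they have at least one index-coded
#' visit, (b) the first such visit falls after the washout window, (c) no
#' index-coded visit falls inside the washout window, and (d) age at that
#' first visit does not exceed `max_age_years`. Age is computed as diagnosis
#' year minus birth year. The period before diagnosis — the length of record
#' history available before the first index-coded visit — is returned in
#' years; it is the matching covariate that equalizes comorbidity
#' ascertainment windows between cases and controls.
#'
#' @param x A [claims_set()] of complete patients (see [filter_complete()]).
#' @param spec A [cohort_spec()].
#' @return Tibble with one row per incident case: `patient_id`,
#'   `diagnosis_date`, `age_at_diagnosis`, `period_before_diagnosis`
#'   (years), plus `sex`, `birth_year` and `first_record_date` for
#'   downstream stages.
#' @export
find_incident_cases <- function(x, spec) {
  stopifnot(inherits(x, "claims_set"), inherits(spec, "cohort_spec"))
  cl <- x$claims
  idx <- cl[match_index_codes(cl$icd10_code, spec$index_codes), ]
  if (nrow(idx) == 0) {
    return(tibble::tibble(patient_id = character(), diagnosis_date = as.Date(character()),
                          age_at_diagnosis = integer(),
                          period_before_diagnosis = numeric(),
                          sex = character(), birth_year = integer(),
                          first_record_date = as.Date(character())))
  }
  per <- dplyr::summarise(
    dplyr::group_by(idx, .data$patient_id),
    first_index_date = min(.data$visit_date),
    any_in_washout = any(.data$visit_date >= spec$washout_start &
                           .data$visit_date <= spec$washout_end),
    .groups = "drop"
  )
  first_rec <- dplyr::summarise(
    dplyr::group_by(cl[cl$patient_id %in% per$patient_id, ], .data$patient_id),
    first_record_date = min(.data$visit_date), .groups = "drop"
  )
  per <- dplyr::left_join(per, first_rec, by = "patient_id")
  per <- dplyr::left_join(per, x$patients, by = "patient_id")
  per$age_at_diagnosis <- as.integer(format(per$first_index_date, "%Y")) -
    per$birth_year
  keep <- per$first_index_date > spec$washout_end &
    !per$any_in_washout &
    !is.na(per$age_at_diagnosis) &
    per$age_at_diagnosis <= spec$max_age_years
  per <- per[keep, ]
  tibble::tibble(
    patient_id = per$patient_id,
    diagnosis_date = per$first_index_date,
    age_at_diagnosis = per$age_at_diagnosis,
    period_before_diagnosis =
      as.numeric(per$first_index_date - per$first_record_date) / 365.25,
    sex = per$sex,
    birth_year = per$birth_year,
    first_record_date = per$first_record_date
  )
}

#' Extract pre-diagnosis records for incident cases
#'
#' Returns every claim of each case strictly before its diagnosis date
#' ("prior to" is read as strict: same-day codes are excluded so the
#' diagnostic workup itself is not counted as comorbidity), with index-coded
#' claims removed.
#'
#' @param x A [claims_set()].
#' @param cases Tibble from [find_incident_cases()] (needs `patient_id`,
#'   `diagnosis_date`).
#' @param index_codes Index-disease code prefixes to exclude.
#' @return Tibble of claims (`patient_id`, `visit_date`, `icd10_code`).
#' @export
extract_pre_diagnosis <- function(x, cases,
                                  index_codes = c("M91.1", "M91.8", "M91.9")) {
  stopifnot(inherits(x, "claims_set"))
  if (!all(c("patient_id", "diagnosis_date") %in% names(cases))) {
    stop("`cases` must have columns patient_id and diagnosis_date", call. = FALSE)
  }
  if (anyNA(cases$diagnosis_date)) {
    stop("diagnosis_date missing for ",
         cases$patient_id[which(is.na(cases$diagnosis_date))[1]], call. = FALSE)
  }
  cl <- dplyr::inner_join(x$claims,
                          cases[c("patient_id", "diagnosis_date")],
                          by = "patient_id")
  cl <- cl[cl$visit_date < cl$diagnosis_date &
             !match_index_codes(cl$icd10_code, index_codes), ]
  cl$diagnosis_date <- NULL
  tibble::as_tibble(cl)
}
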