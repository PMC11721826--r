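# The claims_set container: one table of patients, one table of dated
# ICD-10-coded encounters. This is the atomic input of every pipeline stage.

#' Construct a claims set
#'
#' Bundles patient demographics with their coded encounters. A patient is
#' *complete* when both demographic fields are present and the patient has at
#' least one dated visit; incomplete patients are retained (real claims
#' extracts contain them) and dropped explicitly by [filter_complete()].
#'
#' @param patients Data frame with columns `patient_id` (character, unique),
#'   `sex` (`"M"`/`"F"`, `NA` allowed) and `birth_year` (integer, `NA`
#'   allowed).
#' @param claims Data frame with columns `patient_id`, `visit_date` (`Date`)
#'   and `icd10_code` (three-character category, optionally subdivided, e.g.
#'   `"M91.1"`). Every `patient_id` must appear in `patients`.
#' @return An object of class `claims_set`: a list with tibbles `patients`
#'   and `claims` (claims sorted by patient and date).
#' @export
#' @examples
#' cs <- claims_set(
#'   patients = data.frame(patient_id = "P1", sex = "M", birth_year = 2000L),
#'   claims = data.frame(patient_id = "P1",
#'                       visit_date = as.Date("2005-03-01"),
#'                       icd10_code = "J45")
#' )
#' cs
claims_set <- function(patients, claims) {
  patients <- tibble::as_tibble(patients)
  claims <- tibble::as_tibble(claims)
  need_p <- c("patient_id", "sex", "birth_year")
  need_c <- c("patient_id", "visit_date", "icd10_code")
  check_that(all(need_p %in% names(patients)), "patients",
             paste("must have columns", paste(need_p, collapse = ", ")))
  check_that(all(need_c %in% names(claims)), "claims",
             paste("must have columns", paste(need_c, collapse = ", ")))
  check_that(!anyDuplicated(patients$patient_id), "patients",
             "patient_id must be unique")
  check_that(all(patients$sex %in% c("M", "F") | is.na(patients$sex)),
             "patients", "sex must be \"M\", \"F\" or NA")
  check_that(inherits(claims$visit_date, "Date"), "claims",
             "visit_date must be a Date")
  if (nrow(claims)) {
    check_that(!anyNA(claims$visit_date), "claims", "visit_date contains NA")
    bad <- claims$icd10_code[!is_valid_icd10(claims$icd10_code)]
    check_that(length(bad) == 0, "claims",
               paste("invalid ICD-10 code(s):",
                     paste(utils::head(unique(bad), 5), collapse = ", ")))
    orphan <- setdiff(claims$patient_id, patients$patient_id)
    check_that(length(orphan) == 0, "claims",
               paste("patient_id not in patients:",
                     paste(utils::head(orphan, 5), collapse = ", ")))
    claims <- dplyr::arrange(claims, .data$patient_id, .data$visit_date,
                             .data$icd10_code)
  }
  patients$birth_year <- as.integer(patients$birth_year)
  structure(list(patients = patients[need_p], claims = claims[need_c]),
            class = "claims_set")
}

#' @export
print.claims_set <- function(x, ...) {
  cf <- complete_flags(x)
  cat(sprintf("<claims_set> %d patients (%d complete), %d claims, %d distinct codes\n",
              nrow(x$patients), sum(cf), nrow(x$claims),
              dplyr::n_distinct(x$claims$icd10_code)))
  if (nrow(x$claims)) {
    cat(sprintf("  visit dates %s to %s\n",
                min(x$claims$visit_date), max(x$claims$visit_date)))
  }
  invisible(x)
}

#' Per-patient completeness flags
#'
#' A patient is complete when sex and birth year are recorded and the patient
#' has at least one visit during the observation period.
#'
#' @param x A [claims_set()].
#' @return Named logical vector, one element per patient (in `x$patients`
#'   order).
#' @export
complete_flags <- function(x) {
  stopifnot(inherits(x, "claims_set"))
  has_visit <- x$patients$patient_id %in% x$claims$patient_id
  ok <- !is.na(x$patients$sex) & !is.na(x$patients$birth_year) & has_visit
  stats::setNames(ok, x$patients$patient_id)
}

#' Drop incomplete patients
#'
#' Removes patients missing demographic data or with no recorded visit,
#' together with their claims (visits of demographically incomplete patients
#' cannot enter any case or control group).
#'
#' @param x A [claims_set()].
#' @return A `claims_set` containing exactly the complete patients.
#' @export
filter_complete <- function(x) {
  keep <- complete_flags(x)
  claims_set(x$patients[keep, ],
             x$claims[x$claims$patient_id %in% x$patients$patient_id[keep], ])
}

#' Write a claims set to delimited text
#'
#' One row per coded encounter, columns `patient_id`, `sex`, `birth_year`,
#' `visit_date` (ISO-8601), `icd10_code`. Patients without any visit are
#' preserved as a single row with empty visit fields so that
#' `read_claims(write_claims(x))` round-trips exactly.
#'
#' @param x A [claims_set()].
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_claims <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "claims_set"), delim %in% c(",", "\t"))
  rows <- dplyr::left_join(x$claims, x$patients, by = "patient_id")
  visitless <- x$patients[!x$patients$patient_id %in% x$claims$patient_id, ]
  if (nrow(visitless)) {
    visitless$visit_date <- as.Date(NA)
    visitless$icd10_code <- NA_character_
    rows <- dplyr::bind_rows(rows, visitless)
  }
  rows <- dplyr::arrange(rows, .data$patient_id, .data$visit_date,
                         .data$icd10_code)
  out <- rows[c("patient_id", "sex", "birth_year", "visit_date", "icd10_code")]
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Read a claims set from delimited text
#'
#' Reads the schema written by [write_claims()]; the delimiter (comma or tab)
#' is detected from the header line. Malformed dates, codes or sex tokens are
#' reported with their line number.
#'
#' @param path Path to a claims file.
#' @return A [claims_set()].
#' @export
read_claims <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty claims file: ", path, call. = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, na = "", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      sex = readr::col_character(),
      birth_year = readr::col_integer(),
      visit_date = readr::col_character(),
      icd10_code = readr::col_character()
    )
  )
  need <- c("patient_id", "sex", "birth_year", "visit_date", "icd10_code")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("claims file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1

  bad_sex <- which(!(raw$sex %in% c("M", "F")) & !is.na(raw$sex))
  if (length(bad_sex)) {
    stop(sprintf("line %d: unknown sex token \"%s\" (expected M, F or empty)",
                 line_no[bad_sex[1]], raw$sex[bad_sex[1]]), call. = FALSE)
  }
  has_visit <- !is.na(raw$visit_date) | !is.na(raw$icd10_code)
  date <- as.Date(rep(NA, nrow(raw)))
  date[has_visit] <- as.Date(raw$visit_date[has_visit],
                             format = "%Y-%m-%d", optional = TRUE)
  bad_date <- which(has_visit & is.na(date))
  if (length(bad_date)) {
    stop(sprintf("line %d: malformed visit_date \"%s\" (expected YYYY-MM-DD)",
                 line_no[bad_date[1]], raw$visit_date[bad_date[1]]),
         call. = FALSE)
  }
  bad_code <- which(has_visit & !is_valid_icd10(raw$icd10_code))
  if (length(bad_code)) {
    stop(sprintf("line %d: malformed icd10_code \"%s\"",
                 line_no[bad_code[1]], raw$icd10_code[bad_code[1]]),
         call. = FALSE)
  }

  patients <- dplyr::distinct(raw[c("patient_id", "sex", "birth_year")])
  if (anyDuplicated(patients$patient_id)) {
    dup <- patients$patient_id[duplicated(patients$patient_id)][1]
    stop("inconsistent demographics for patient ", dup, call. = FALSE)
  }
  claims <- raw[has_visit, c("patient_id", "icd10_code")]
  claims$visit_date <- date[has_visit]
  claims_set(patients, claims)
}
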