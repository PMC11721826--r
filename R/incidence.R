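# Annual incidence per 100,000 by sex with a washout year.

#' Annual incidence of the index disease by sex
#'
#' A patient contributes a new case in year `Y` iff their first index-coded
#' visit falls in `Y` (the first visit has, by definition, no earlier
#' index-coded visit; the washout is enforced by excluding the first
#' `washout_years` calendar year(s) of the database from `years`) and their
#' age in `Y` does not exceed `max_age`. The at-risk denominator is the
#' number of age-eligible patients of that sex not yet index-diagnosed
#' before `Y`; the rate is new cases per 100,000 such patients.
#'
#' @param x A [claims_set()] (patients with missing sex or birth year are
#'   excluded from both numerator and denominator).
#' @param index_codes Index-disease code prefixes.
#' @param years Integer vector of calendar years to report; must not include
#'   the washout year(s).
#' @param washout_years Length of the initial washout (default 1 year).
#' @param max_age Maximum eligible age in years.
#' @return Tibble `year`, `sex`, `n_new_cases`, `population_at_risk`,
#'   `rate_per_100k`.
#' @export
annual_incidence <- function(x, index_codes = c("M91.1", "M91.8", "M91.9"),
                             years, washout_years = 1L, max_age = 12L) {
  stopifnot(inherits(x, "claims_set"))
  if (nrow(x$claims) == 0) stop("claims set has no claims", call. = FALSE)
  first_year <- as.integer(format(min(x$claims$visit_date), "%Y"))
  if (any(years < first_year + washout_years)) {
    stop("`years` must exclude the washout year(s) ",
         paste(seq(first_year, length.out = washout_years), collapse = ", "),
         call. = FALSE)
  }
  pats <- x$patients[!is.na(x$patients$sex) & !is.na(x$patients$birth_year), ]
  idx <- x$claims[match_index_codes(x$claims$icd10_code, index_codes), ]
  first_idx <- if (nrow(idx)) {
    dplyr::summarise(dplyr::group_by(idx, .data$patient_id),
                     first_index_date = min(.data$visit_date),
                     .groups = "drop")
  } else {
    tibble::tibble(patient_id = character(),
                   first_index_date = as.Date(character()))
  }
  pats <- dplyr::left_join(pats, first_idx, by = "patient_id")
  pats$first_index_year <- as.integer(format(pats$first_index_date, "%Y"))

  out <- vector("list", length(years) * 2L)
  k <- 0L
  for (y in sort(unique(as.integer(years)))) {
    age <- y - pats$birth_year
    eligible <- age >= 0L & age <= max_age &
      (is.na(pats$first_index_year) | pats$first_index_year >= y)
    new_case <- eligible & !is.na(pats$first_index_year) &
      pats$first_index_year == y
    for (s in c("M", "F")) {
      denom <- sum(eligible & pats$sex == s)
      if (denom == 0) {
        stop("no at-risk patients of sex ", s, " in year ", y, call. = FALSE)
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        year = y, sex = s,
        n_new_cases = sum(new_case & pats$sex == s),
        population_at_risk = denom,
        rate_per_100k = 1e5 * sum(new_case & pats$sex == s) / denom
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Exact test of male vs female incidence
#'
#' Pools case counts and at-risk person-years over the reported years and
#' tests equality of the male and female rates with the exact conditional
#' binomial test: given the total number of cases, the male share is
#' binomial with success probability equal to the male fraction of
#' person-years under the null of equal rates.
#'
#' @param table An [annual_incidence()] table containing both sexes.
#' @return Two-sided p-value.
#' @export
sex_rate_comparison <- function(table) {
  need <- c("year", "sex", "n_new_cases", "population_at_risk")
  stopifnot(all(need %in% names(table)))
  for (s in c("M", "F")) {
    if (!any(table$sex == s)) stop("sex ", s, " absent from table", call. = FALSE)
  }
  cases_m <- sum(table$n_new_cases[table$sex == "M"])
  cases_f <- sum(table$n_new_cases[table$sex == "F"])
  py_m <- sum(table$population_at_risk[table$sex == "M"])
  py_f <- sum(table$population_at_risk[table$sex == "F"])
  if (cases_m + cases_f == 0) return(1)
  stats::binom.test(cases_m, cases_m + cases_f,
                    p = py_m / (py_m + py_f))$p.value
}
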