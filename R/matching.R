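# 1:3 propensity-score matching: logistic score on age, sex and period
# before diagnosis; greedy nearest-neighbor without replacement, exact on
# sex; matched pseudo-index dates so control ascertainment windows equal
# their case's pre-diagnosis period.

#' Matching settings
#'
#' @param ratio Controls per case (fixed ratio, without replacement).
#' @param exact_sex Match within sex strata (gives identical case/control
#'   sex proportions, as nearest-neighbor distance on the score alone cannot
#'   reliably do).
#' @param caliper Optional maximum |score difference|; `NULL` (default)
#'   disables it.
#' @param seed Integer seed for tie-breaking; same seed gives an identical
#'   matched cohort.
#' @return An object of class `match_spec`.
#' @export
match_spec <- function(ratio = 3L, exact_sex = TRUE, caliper = NULL, seed = 1L) {
  check_that(is.numeric(ratio) && ratio >= 1, "ratio", "must be >= 1")
  if (!is.null(caliper)) {
    check_that(caliper > 0, "caliper", "must be > 0")
  }
  structure(list(ratio = as.integer(ratio), exact_sex = isTRUE(exact_sex),
                 caliper = caliper, seed = as.integer(seed)),
            class = "match_spec")
}

#' Build the control candidate pool
#'
#' Candidates are complete patients never coded for the index disease. Each
#' is assigned a seeded reference date, uniform over their record span, at
#' which age and available record period are evaluated — giving candidates
#' the same covariate definitions as cases (whose reference is the diagnosis
#' date). Candidates age-ineligible at their reference date are dropped.
#'
#' @param x A [claims_set()] of complete patients.
#' @param cases Tibble from [find_incident_cases()]; its patients are
#'   excluded from the pool.
#' @param spec A [cohort_spec()] (supplies index codes, age limit and
#'   observation end).
#' @param seed Integer seed for the reference-date draw.
#' @return Tibble `patient_id`, `sex`, `age`, `period`, `first_record_date`.
#' @export
control_candidates <- function(x, cases, spec, seed = 1L) {
  stopifnot(inherits(x, "claims_set"), inherits(spec, "cohort_spec"))
  withr::local_seed(seed)
  ever_index <- unique(
    x$claims$patient_id[match_index_codes(x$claims$icd10_code, spec$index_codes)]
  )
  first_rec <- dplyr::summarise(dplyr::group_by(x$claims, .data$patient_id),
                                first_record_date = min(.data$visit_date),
                                .groups = "drop")
  pool <- dplyr::inner_join(x$patients, first_rec, by = "patient_id")
  pool <- pool[!pool$patient_id %in% c(ever_index, cases$patient_id), ]
  pool <- pool[!is.na(pool$sex) & !is.na(pool$birth_year), ]
  span <- as.numeric(spec$observation_end - pool$first_record_date)
  ref <- pool$first_record_date + floor(stats::runif(nrow(pool)) * (span + 1))
  age <- as.integer(format(ref, "%Y")) - pool$birth_year
  keep <- age >= 0L & age <= spec$max_age_years
  tibble::tibble(
    patient_id = pool$patient_id[keep],
    sex = pool$sex[keep],
    age = age[keep],
    period = as.numeric(ref[keep] - pool$first_record_date[keep]) / 365.25,
    first_record_date = pool$first_record_date[keep]
  )
}

#' Estimate propensity scores
#'
#' Fits a logistic regression of case status on age, sex and period before
#' diagnosis over the stacked cases and candidates, and returns the fitted
#' probabilities as the matching score.
#'
#' @param cases Tibble from [find_incident_cases()] (uses `patient_id`,
#'   `sex`, `age_at_diagnosis` as age, `period_before_diagnosis` as period,
#'   `first_record_date`).
#' @param candidates Tibble from [control_candidates()].
#' @return Tibble of all patients with `role` (`"case"`/`"candidate"`),
#'   covariates and `score` in (0, 1).
#' @export
estimate_propensity <- function(cases, candidates) {
  stopifnot(nrow(cases) >= 1)
  if (nrow(candidates) < nrow(cases)) {
    stop("candidate pool smaller than the case group", call. = FALSE)
  }
  stacked <- dplyr::bind_rows(
    tibble::tibble(patient_id = cases$patient_id, role = "case",
                   sex = cases$sex, age = as.numeric(cases$age_at_diagnosis),
                   period = cases$period_before_diagnosis,
                   first_record_date = cases$first_record_date),
    tibble::tibble(patient_id = candidates$patient_id, role = "candidate",
                   sex = candidates$sex, age = as.numeric(candidates$age),
                   period = candidates$period,
                   first_record_date = candidates$first_record_date)
  )
  y <- as.integer(stacked$role == "case")
  varying <- vapply(stacked[c("age", "sex", "period")],
                    function(v) length(unique(v)) > 1, logical(1))
  form <- if (any(varying)) {
    stats::reformulate(names(varying)[varying], response = "y")
  } else {
    y ~ 1
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = cbind(stacked, y = y)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep || !fit$converged) {
    stop("propensity model separates cases from candidates perfectly; ",
         "review the covariates", call. = FALSE)
  }
  stacked$score <- as.numeric(stats::fitted(fit))
  stacked
}

#' Assign a control's pseudo-index date
#'
#' The pseudo-index date mirrors the matched case's pre-diagnosis period:
#' first observed record date plus that period. Comorbidity ascertainment
#' for the control uses records strictly before this date, so case and
#' control windows have equal length by construction.
#'
#' @param first_record_date Control's first observed record date (`Date`).
#' @param period_years Matched case's period before diagnosis, in years.
#' @return `Date` vector of pseudo-index dates.
#' @export
#' @examples
#' assign_pseudo_index(as.Date("2005-01-01"), 3)
assign_pseudo_index <- function(first_record_date, period_years) {
  stopifnot(inherits(first_record_date, "Date"), all(period_years >= 0))
  first_record_date + floor(period_years * 365.25 + 1e-9)
}

#' Greedy nearest-neighbor matching
#'
#' Cases are processed in descending propensity-score order (hardest to
#' match first); each takes its `ratio` nearest unused candidates by
#' absolute score difference within the same sex stratum (when `exact_sex`),
#' ties broken by a seeded draw. Candidates whose record span cannot
#' accommodate the case's pre-diagnosis period before `observation_end` are
#' skipped, so every control receives a valid pseudo-index date.
#'
#' @param scores Stacked tibble from [estimate_propensity()].
#' @param spec A [match_spec()].
#' @param observation_end Last day of observation; `NULL` disables the
#'   window-feasibility check.
#' @return An object of class `matched_cohort`: list with tibbles `cases`,
#'   `controls` (`patient_id`, `matched_case_id`, `score`,
#'   `pseudo_index_date`) and `balance` (per-covariate standardized mean
#'   differences).
#' @export
greedy_match <- function(scores, spec = match_spec(), observation_end = NULL) {
  stopifnot(inherits(spec, "match_spec"))
  withr::local_seed(spec$seed)
  cases <- scores[scores$role == "case", ]
  cand <- scores[scores$role == "candidate", ]
  tiebreak <- stats::runif(nrow(cand))
  case_order <- order(-cases$score, stats::runif(nrow(cases)))
  used <- rep(FALSE, nrow(cand))
  feas_days <- if (is.null(observation_end)) {
    rep(Inf, nrow(cand))
  } else {
    as.numeric(as.Date(observation_end) - cand$first_record_date)
  }
  picks <- vector("list", nrow(cases))
  for (i in case_order) {
    ok <- !used &
      feas_days >= cases$period[i] * 365.25 - 1e-9
    if (spec$exact_sex) ok <- ok & cand$sex == cases$sex[i]
    d <- abs(cand$score - cases$score[i])
    if (!is.null(spec$caliper)) ok <- ok & d <= spec$caliper
    idx <- which(ok)
    if (length(idx) < spec$ratio) {
      stratum <- if (spec$exact_sex) paste("sex", cases$sex[i]) else "pool"
      stop(sprintf("matching stratum exhausted (%s): need %d controls for case %s, %d available",
                   stratum, spec$ratio, cases$patient_id[i], length(idx)),
           call. = FALSE)
    }
    sel <- idx[order(d[idx], tiebreak[idx])[seq_len(spec$ratio)]]
    used[sel] <- TRUE
    picks[[i]] <- tibble::tibble(
      patient_id = cand$patient_id[sel],
      matched_case_id = cases$patient_id[i],
      sex = cand$sex[sel],
      age = cand$age[sel],
      period = cases$period[i],  # ascertainment window mirrors the case
      score = cand$score[sel],
      pseudo_index_date = assign_pseudo_index(cand$first_record_date[sel],
                                              cases$period[i])
    )
  }
  controls <- dplyr::bind_rows(picks)
  controls <- dplyr::arrange(controls, .data$matched_case_id, .data$patient_id)
  out <- structure(list(cases = cases, controls = controls,
                        balance = covariate_balance(cases, controls),
                        ratio = spec$ratio),
                   class = "matched_cohort")
  out
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d cases, %d controls (1:%d)\n",
              nrow(x$cases), nrow(x$controls), x$ratio))
  print(x$balance)
  invisible(x)
}

#' Covariate balance of a matched cohort
#'
#' Standardized mean differences (SMD) between cases and matched controls
#' for age, sex (male indicator) and period before diagnosis:
#' `(mean_case - mean_control) / sqrt((var_case + var_control) / 2)`. SMD
#' below 0.1 is the conventional threshold for adequate balance.
#'
#' @param cases,controls Tibbles with columns `sex`, `age`, `period`
#'   (cases from [estimate_propensity()] stacking, controls from
#'   [greedy_match()]).
#' @return Tibble `covariate`, `mean_cases`, `mean_controls`, `smd`.
#' @export
covariate_balance <- function(cases, controls) {
  smd1 <- function(a, b) {
    s <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (!is.finite(s) || s == 0) return(0)
    (mean(a) - mean(b)) / s
  }
  vals <- list(
    age = list(cases$age, controls$age),
    sex_male = list(as.numeric(cases$sex == "M"), as.numeric(controls$sex == "M")),
    period = list(cases$period, controls$period)
  )
  tibble::tibble(
    covariate = names(vals),
    mean_cases = unname(vapply(vals, function(v) mean(v[[1]]), numeric(1))),
    mean_controls = unname(vapply(vals, function(v) mean(v[[2]]), numeric(1))),
    smd = unname(vapply(vals, function(v) smd1(v[[1]], v[[2]]), numeric(1)))
  )
}
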