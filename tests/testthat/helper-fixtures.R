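# Shared fixture builders: tiny hand-built claims sets used across modules.

mk_patients <- function(ids, sex = "M", birth_year = 2000L) {
  tibble::tibble(patient_id = ids,
                 sex = rep_len(sex, length(ids)),
                 birth_year = rep_len(as.integer(birth_year), length(ids)))
}

mk_claims <- function(ids, dates, codes) {
  tibble::tibble(patient_id = ids, visit_date = as.Date(dates),
                 icd10_code = codes)
}

# a small complete claims set: 3 patients, mixed codes
toy_claims_set <- function() {
  claims_set(
    mk_patients(c("A", "B", "C"), sex = c("M", "F", "M"),
                birth_year = c(1998L, 2000L, 2002L)),
    mk_claims(
      c("A", "A", "A", "B", "B", "C"),
      c("2003-05-01", "2005-06-10", "2006-01-02",
        "2004-03-03", "2007-08-09", "2005-12-31"),
      c("J45.0", "M91.1", "M91.1", "J06", "M91.9", "A09")
    )
  )
}

# fast generator settings for tests that only need a modest cohort
small_sim <- function(seed, n = 2000, rate = 300, planted = NULL,
                      missing = 0.05) {
  sim_config(
    n_patients = n,
    study_start = as.Date("2002-01-01"), study_end = as.Date("2009-12-31"),
    age_range = c(-7L, 12L), visit_rate = 1, condition_visit_rate = 1.5,
    code_catalog = tibble::tibble(
      icd10_code = c("J06", "A09", "D64", "M67", "Q65"),
      baseline_prevalence = c(0.35, 0.2, 0.05, 0.05, 0.03)
    ),
    index_disease = index_disease_spec(incidence_female_per_100k = rate),
    planted_effects = planted,
    missingness_fraction = missing,
    seed = seed
  )
}

# run the generator output through cohort + matching + association, the
# chain used by several stochastic checks
run_stages <- function(cs, spec = demo_cohort_spec(), seed = 1,
                       ratio = 3L, alpha = 0.05) {
  cc <- filter_complete(cs)
  cases <- find_incident_cases(cc, spec)
  cand <- control_candidates(cc, cases, spec, seed = seed + 1000)
  ps <- estimate_propensity(cases, cand)
  mc <- greedy_match(ps, match_spec(ratio = ratio, seed = seed + 2000),
                     observation_end = spec$observation_end)
  case_recs <- extract_pre_diagnosis(cc, cases, spec$index_codes)
  ctrl_cut <- tibble::tibble(patient_id = mc$controls$patient_id,
                             diagnosis_date = mc$controls$pseudo_index_date)
  ctrl_recs <- extract_pre_diagnosis(cc, ctrl_cut, spec$index_codes)
  pm <- presence_matrix(case_recs, ctrl_recs, cases$patient_id,
                        mc$controls$patient_id)
  list(cases = cases, matched = mc, pm = pm,
       results = screen_clusters(pm, alpha = alpha))
}
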