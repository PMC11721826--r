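test_that("sim_config rejects invalid fields, naming the field", {
  expect_error(sim_config(male_fraction = 1.2), "male_fraction")
  expect_error(sim_config(study_start = "2010-01-01", study_end = "2002-01-01"),
               "study_start")
  expect_error(sim_config(missingness_fraction = -0.1), "missingness_fraction")
  expect_error(sim_config(planted_effects = data.frame(code = "X99", odds_ratio = 2)),
               "planted_effects")
  expect_error(sim_config(planted_effects = data.frame(code = "J45", odds_ratio = 0),
                          code_catalog = data.frame(icd10_code = "J45",
                                                    baseline_prevalence = 0.1)),
               "planted_effects")
  expect_error(sim_config(code_catalog = data.frame(icd10_code = "J45",
                                                    baseline_prevalence = 1.5)),
               "code_catalog")
  expect_error(
    sim_config(code_catalog = data.frame(icd10_code = c("J45", "A09"),
                                         baseline_prevalence = 0.1),
               pairwise_effects = data.frame(code_a = "J45", code_b = "A09",
                                             odds_ratio = -1)),
    "pairwise_effects")
})

test_that("generator configs read back from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 500",
    "study_start: 2002-01-01",
    "study_end: 2009-12-31",
    "age_range: [-7, 12]",
    "code_catalog:",
    "  - {icd10_code: J06, baseline_prevalence: 0.3}",
    "  - {icd10_code: Q65, baseline_prevalence: 0.05}",
    "index_disease: {incidence_female_per_100k: 200}",
    "planted_effects:",
    "  - {code: Q65, odds_ratio: 5}",
    "seed: 7"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_patients, 500L)
  expect_equal(cfg$planted_effects$odds_ratio, 5)
  expect_equal(cfg$index_disease$incidence_female_per_100k, 200)
  # reading is faithful: generating from it matches the in-R construction
  direct <- sim_config(n_patients = 500, study_start = "2002-01-01",
                       study_end = "2009-12-31", age_range = c(-7L, 12L),
                       code_catalog = cfg$code_catalog,
                       index_disease = index_disease_spec(incidence_female_per_100k = 200),
                       planted_effects = data.frame(code = "Q65", odds_ratio = 5),
                       seed = 7)
  expect_identical(generate_claims(cfg)$claims, generate_claims(direct)$claims)

  writeLines("bogus_field: 3", path)
  expect_error(read_sim_config(path), "bogus_field")
})

test_that("the same config and seed reproduce the dataset exactly", {
  cfg <- small_sim(seed = 7, n = 400)
  a <- generate_claims(cfg)
  b <- generate_claims(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$claims, b$claims)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  c_ <- generate_claims(small_sim(seed = 8, n = 400))
  expect_false(identical(a$claims, c_$claims))
})

test_that("generated claims respect the study window and the code pattern", {
  cfg <- small_sim(seed = 3, n = 800)
  cs <- generate_claims(cfg)
  expect_true(all(cs$claims$visit_date >= cfg$study_start))
  expect_true(all(cs$claims$visit_date <= cfg$study_end))
  expect_true(all(grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$", cs$claims$icd10_code)))
  # no one is coded before their (known) birth year
  joined <- dplyr::inner_join(cs$claims, cs$patients, by = "patient_id")
  joined <- joined[!is.na(joined$birth_year), ]
  expect_true(all(as.integer(format(joined$visit_date, "%Y")) >= joined$birth_year))
})

test_that("index-case sex ratio follows the configured male multiplier", {
  cfg <- small_sim(seed = 5, n = 20000, rate = 200)
  tr <- attr(generate_claims(cfg), "truth")
  cases <- tr[tr$is_case, ]
  mult <- cfg$index_disease$male_case_multiplier
  p_male <- 0.5 * mult / (0.5 * mult + 0.5)
  ci <- binom.test(sum(cases$sex == "M"), nrow(cases))$conf.int
  expect_gt(p_male, ci[1])
  expect_lt(p_male, ci[2])
})

test_that("without planted effects, case and control code carriage is exchangeable", {
  cfg <- small_sim(seed = 11, n = 20000, rate = 300, planted = NULL, missing = 0)
  cs <- generate_claims(cfg)
  tr <- attr(cs, "truth")
  # presence of a catalog code anywhere in the record, cases vs controls
  for (code in c("D64", "M67")) {
    carrier <- unique(cs$claims$patient_id[startsWith(cs$claims$icd10_code, code)])
    a <- sum(tr$is_case & tr$patient_id %in% carrier)
    b <- sum(tr$is_case) - a
    c_ <- sum(!tr$is_case & tr$patient_id %in% carrier)
    d <- sum(!tr$is_case) - c_
    ci <- suppressWarnings(fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE)))
    expect_gt(ci$conf.int[2], 1)
    expect_lt(ci$conf.int[1], 1)
  }
})

test_that("a single planted odds ratio tilts carriage as configured", {
  cfg <- small_sim(seed = 13, n = 20000, rate = 300,
                   planted = data.frame(code = "M67", odds_ratio = 5),
                   missing = 0)
  cs <- generate_claims(cfg)
  tr <- attr(cs, "truth")
  carrier <- unique(cs$claims$patient_id[startsWith(cs$claims$icd10_code, "M67")])
  a <- sum(tr$is_case & tr$patient_id %in% carrier)
  b <- sum(tr$is_case) - a
  c_ <- sum(!tr$is_case & tr$patient_id %in% carrier)
  d <- sum(!tr$is_case) - c_
  ci <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$conf.int
  expect_gt(ci[2], 5)
  expect_lt(ci[1], 5)
})

test_that("the Plackett joint construction hits the requested pairwise odds ratio", {
  # closed-form root satisfies the 2x2 odds-ratio identity ...
  for (pa in c(0.05, 0.3, 0.6)) {
    for (psi in c(0.5, 1, 4, 10)) {
      pb <- 0.2
      p11 <- comorbnet:::plackett_p11(pa, pb, psi)
      expect_gte(p11, max(0, pa + pb - 1) - 1e-12)
      expect_lte(p11, min(pa, pb) + 1e-12)
      or <- (p11 * (1 - pa - pb + p11)) / ((pa - p11) * (pb - p11))
      expect_equal(or, psi, tolerance = 1e-8)
    }
  }
  # ... and generated carriage indicators reflect it
  cfg <- small_sim(seed = 17, n = 20000, rate = 50, missing = 0)
  cfg2 <- sim_config(
    n_patients = cfg$n_patients, study_start = cfg$study_start,
    study_end = cfg$study_end, age_range = cfg$age_range,
    visit_rate = cfg$visit_rate, condition_visit_rate = cfg$condition_visit_rate,
    code_catalog = cfg$code_catalog, index_disease = cfg$index_disease,
    pairwise_effects = data.frame(code_a = "J06", code_b = "A09", odds_ratio = 3),
    missingness_fraction = 0, seed = 17
  )
  cs <- generate_claims(cfg2)
  ids <- cs$patients$patient_id
  ha <- ids %in% cs$claims$patient_id[startsWith(cs$claims$icd10_code, "J06")]
  hb <- ids %in% cs$claims$patient_id[startsWith(cs$claims$icd10_code, "A09")]
  ci <- fisher.test(table(ha, hb))$conf.int
  expect_gt(ci[2], 3)
  expect_lt(ci[1], 3)
})

test_that("simulate_presence is seeded and honors prevalences and tilts", {
  prev <- c(J45 = 0.3, D64 = 0.05)
  a <- simulate_presence(200, 600, prev, case_odds_ratio = c(1, 4), seed = 9)
  b <- simulate_presence(200, 600, prev, case_odds_ratio = c(1, 4), seed = 9)
  expect_identical(a$indicators, b$indicators)
  expect_equal(dim(a$indicators), c(800L, 2L))
  expect_equal(sum(a$is_case), 200L)
  # control prevalence near nominal
  expect_lt(abs(mean(a$indicators[!a$is_case, "J45"]) - 0.3), 0.08)
})
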