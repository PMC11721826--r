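# Independent hypergeometric enumeration oracle for the two-sided Fisher
# test (point-probability rule).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b            # case margin
  k <- a + c            # exposed margin
  n <- a + b + c + d
  lo <- max(0, k - (n - m))
  hi <- min(k, m)
  x <- lo:hi
  pr <- dhyper(x, m, n - m, k)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

test_that("ICD-10 codes truncate to three-character categories", {
  expect_equal(truncate_icd10("M91.1"), "M91")
  expect_equal(truncate_icd10("J45"), "J45")
  expect_equal(truncate_icd10("j45.02"), "J45")
  x <- c("M91.1", "S72.01", "A09")
  expect_equal(truncate_icd10(truncate_icd10(x)), truncate_icd10(x))
  expect_error(truncate_icd10("45J"), "45J")
  expect_error(truncate_icd10("M9"), "M9")
})

test_that("presence is per-patient, once per cluster", {
  # five visits across two subdivisions of one category -> one indicator
  recs_case <- mk_claims(rep("p1", 5),
                         paste0("2005-0", 1:5, "-01"),
                         c("J45.0", "J45.1", "J45.0", "J45.1", "J45.0"))
  pm <- presence_matrix(recs_case, mk_claims("q1", "2005-01-01", "A09"))
  expect_equal(dim(pm$indicators), c(2L, 2L))
  expect_equal(sum(pm$indicators["p1", ]), 1)
  expect_true(pm$indicators["p1", "J45"])

  # an empty record list gives an all-zero row
  pm <- presence_matrix(recs_case, mk_claims(character(), as.Date(character()),
                                             character()),
                        case_ids = "p1", control_ids = "q9")
  expect_equal(unname(rowSums(pm$indicators)["q9" == rownames(pm$indicators)]), 0)

  # toy cohort equals a hand-enumerated oracle
  recs_case <- mk_claims(c("p1", "p1", "p2", "p3"),
                         rep("2005-01-01", 4),
                         c("J45", "A09", "A09", "D64.0"))
  recs_ctrl <- mk_claims(c("q1", "q2", "q2"),
                         rep("2005-01-01", 3),
                         c("J45", "D64", "M67"))
  pm <- presence_matrix(recs_case, recs_ctrl,
                        case_ids = c("p1", "p2", "p3"),
                        control_ids = c("q1", "q2"))
  want <- rbind(
    p1 = c(A09 = TRUE, D64 = FALSE, J45 = TRUE, M67 = FALSE),
    p2 = c(TRUE, FALSE, FALSE, FALSE),
    p3 = c(FALSE, TRUE, FALSE, FALSE),
    q1 = c(FALSE, FALSE, TRUE, FALSE),
    q2 = c(FALSE, TRUE, FALSE, TRUE)
  )
  colnames(want) <- c("A09", "D64", "J45", "M67")
  expect_equal(pm$indicators, want)
  expect_equal(pm$is_case, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("the Haldane-Anscombe correction is applied to every cell, unconditionally", {
  expect_equal(round(haldane_anscombe_or(4, 163, 0, 501), 2), 27.61)
  expect_equal(round(haldane_anscombe_or(8, 159, 7, 494), 2), 3.51)
  # without the correction the same table gives 3.55: the correction must
  # apply even when no cell is zero
  expect_equal(round((8 * 494) / (159 * 7), 2), 3.55)
  expect_equal(haldane_anscombe_or(1, 1, 1, 1), 1)
  # exposure-flip reciprocity
  set.seed(3)
  for (i in 1:20) {
    cells <- rpois(4, 20)
    expect_equal(haldane_anscombe_or(cells[1], cells[2], cells[3], cells[4]) *
                   haldane_anscombe_or(cells[2], cells[1], cells[4], cells[3]),
                 1, tolerance = 1e-12)
  }
  expect_error(haldane_anscombe_or(-1, 2, 3, 4), "cell counts")
})

test_that("the two-sided Fisher p matches the enumeration oracle and its symmetries", {
  expect_equal(round(fisher_exact_two_sided(3, 164, 0, 501), 3), 0.015)
  expect_equal(round(fisher_exact_two_sided(4, 163, 0, 501), 3), 0.004)
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1)
  set.seed(4)
  for (i in 1:25) {
    cells <- rpois(4, c(5, 60, 5, 200))
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    p <- fisher_exact_two_sided(a, b, c_, d)
    expect_equal(p, fisher_oracle(a, b, c_, d), tolerance = 1e-9)
    # invariant under simultaneous row and column transposition
    expect_equal(p, fisher_exact_two_sided(d, c_, b, a), tolerance = 1e-12)
    # two-sided p >= the smaller one-sided p
    one_sided <- min(phyper(a, a + b, c_ + d, a + c_),
                     1 - phyper(a - 1, a + b, c_ + d, a + c_))
    expect_gte(p + 1e-12, one_sided)
  }
})

test_that("cluster screening flags planted effects and respects alpha", {
  # a cluster present in no one is absent from the output
  pm <- simulate_presence(100, 300, c(J45 = 0.3, D64 = 0, Q65 = 0.1), seed = 5)
  res <- screen_clusters(pm)
  expect_false("D64" %in% res$cluster)
  expect_equal(res$a + res$b, rep(100L, nrow(res)))

  # equal prevalence in both arms, large n: not significant
  pm <- simulate_presence(2000, 6000, c(J45 = 0.3), seed = 6)
  expect_false(screen_clusters(pm)$significant[1])

  # one planted OR=10 cluster among 50 null clusters at n=668: flagged in
  # >= 95% of 200 seeded replicates
  prev <- setNames(rep(0.05, 51), c("Q65", sprintf("N%02d", 10:59)))
  hits <- 0L
  for (r in 1:200) {
    pm <- simulate_presence(167, 501, prev,
                            case_odds_ratio = c(10, rep(1, 50)), seed = r)
    res <- screen_clusters(pm)
    if (isTRUE(res$significant[res$cluster == "Q65"])) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("regrouping recomputes statistics on union exposure", {
  # union counts 54/167 vs 22/501 give the grouped muscle/synovium OR 10.23
  ind_case <- matrix(FALSE, 167, 3, dimnames = list(sprintf("p%03d", 1:167),
                                                    c("M62", "M65", "M67")))
  ind_case[1:30, "M62"] <- TRUE; ind_case[31:50, "M65"] <- TRUE
  ind_case[51:54, "M67"] <- TRUE
  ind_ctrl <- matrix(FALSE, 501, 3, dimnames = list(sprintf("q%03d", 1:501),
                                                    c("M62", "M65", "M67")))
  ind_ctrl[1:10, "M62"] <- TRUE; ind_ctrl[11:20, "M65"] <- TRUE
  ind_ctrl[21:22, "M67"] <- TRUE
  pm <- comorbnet:::new_presence_matrix(rbind(ind_case, ind_ctrl),
                                        rep(c(TRUE, FALSE), c(167, 501)))
  res <- screen_clusters(pm, alpha = 1)
  grouped <- regroup(res, pm, list("M62/M65/M67" = c("M62", "M65", "M67")))
  expect_equal(grouped$a, 54L)
  expect_equal(grouped$c, 22L)
  expect_equal(round(grouped$odds_ratio, 2), 10.23)
  expect_equal(grouped$anchor, "M62")
  # mutually exclusive member codes: union count = sum of counts
  expect_equal(grouped$a, sum(res$a))

  # singleton group is identical to the ungrouped result
  g1 <- regroup(res, pm, list(M62 = "M62"))
  expect_equal(g1[g1$cluster == "M62", c("a", "c", "odds_ratio", "p_value")],
               res[res$cluster == "M62", c("a", "c", "odds_ratio", "p_value")])
  # passthrough keeps the other clusters unchanged
  expect_setequal(g1$cluster, c("M62", "M65", "M67"))

  expect_error(regroup(res, pm, list(G = c("M62", "ZZZ"))), "ZZZ")
})

test_that("pairwise links are symmetric, calibrated under independence, and powered", {
  # OR(i,j) = OR(j,i): unordered pairs appear once with a canonical order
  pm <- simulate_presence(100, 300, c(A09 = 0.3, J45 = 0.3, L20 = 0.2), seed = 8)
  pw <- pairwise_associations(pm, alpha = 1)
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$cluster_a < pw$cluster_b))
  swapped <- with(pw[1, ], {
    ind <- pm$indicators
    a <- sum(ind[, cluster_b] & ind[, cluster_a])
    b <- sum(ind[, cluster_b] & !ind[, cluster_a])
    c_ <- sum(!ind[, cluster_b] & ind[, cluster_a])
    d <- sum(!ind[, cluster_b] & !ind[, cluster_a])
    haldane_anscombe_or(a, b, c_, d)
  })
  expect_equal(pw$odds_ratio[1], swapped)

  # independent indicators: edge retention rate near alpha; a planted
  # co-occurrence of OR 8 at n=668 is detected in >= 90% of 200 replicates
  solve_p11 <- function(pa, pb, psi) {
    f <- function(x) (x * (1 - pa - pb + x)) / ((pa - x) * (pb - x)) - psi
    uniroot(f, c(max(0, pa + pb - 1) + 1e-9, min(pa, pb) - 1e-9))$root
  }
  p11 <- solve_p11(0.15, 0.15, 8)
  retained <- 0L
  detected <- 0L
  n_pairs_null <- 0L
  set.seed(9)
  for (r in 1:200) {
    n <- 668
    u <- runif(n)
    x1 <- u < 0.15
    x2 <- ifelse(x1, runif(n) < p11 / 0.15, runif(n) < (0.15 - p11) / 0.85)
    ind <- cbind(P01 = x1, P02 = x2,
                 N01 = runif(n) < 0.2, N02 = runif(n) < 0.2,
                 N03 = runif(n) < 0.1)
    rownames(ind) <- sprintf("x%03d", 1:n)
    pm <- comorbnet:::new_presence_matrix(ind, rep(c(TRUE, FALSE), c(167, 501)))
    pw <- pairwise_associations(pm, alpha = 0.05)
    key <- paste(pw$cluster_a, pw$cluster_b)
    if ("P01 P02" %in% key) detected <- detected + 1L
    null_keys <- setdiff(key, "P01 P02")
    # pairs not involving the planted couple are null
    retained <- retained + sum(!grepl("P01|P02", null_keys))
    n_pairs_null <- n_pairs_null + 3L  # N01-N02, N01-N03, N02-N03
  }
  expect_gte(detected / 200, 0.9)
  expect_lte(retained / n_pairs_null, 0.07)
})

test_that("group maps are validated and read from YAML", {
  expect_error(regroup(tibble::tibble(cluster = "A09"), NULL,
                       list(G1 = c("A09"), G2 = c("A09"))), "disjoint")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c('"H16/H60": [H16, H60]', '"D64": [D64]'), path)
  gm <- read_group_map(path)
  expect_equal(gm[["H16/H60"]], c("H16", "H60"))
  writeLines('"G": [H16, H1]', path)
  expect_error(read_group_map(path), "H1")
  expect_equal(sort(unlist(lcpd_group_map(), use.names = FALSE)),
               sort(lcpd_reported_associations()$cluster))
})

test_that("reporting formats follow clinical-table conventions", {
  res <- tibble::tibble(cluster = "Q65", a = 4L, b = 163L, c = 0L, d = 501L,
                        odds_ratio = haldane_anscombe_or(4, 163, 0, 501),
                        p_value = fisher_exact_two_sided(4, 163, 0, 501))
  fmt <- format_results(res)
  expect_equal(fmt$or_fmt, "27.61")
  expect_equal(fmt$p_fmt, "0.004")
  expect_equal(fmt$cases_fmt, "4 (2.4)")
  expect_equal(fmt$controls_fmt, "0 (0.0)")
  expect_equal(format_p(c(0.0005, 0.0164)), c("<0.001", "0.016"))
  expect_equal(round_half_up(c(2.675, 2.665, -2.675), 2), c(2.68, 2.67, -2.68))
})
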