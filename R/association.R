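# Association statistics at the three-character ICD-10 category level:
# presence matrices, Haldane-Anscombe-corrected odds ratios, exact Fisher
# screening, clinical regrouping, pairwise links.

#' Truncate an ICD-10 code to its three-character category
#'
#' Subdivision characters beyond the third are dropped; three-character
#' categories ("disease clusters") are the unit of all association analyses.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Uppercased three-character categories.
#' @export
#' @examples
#' truncate_icd10(c("M91.1", "j45"))
truncate_icd10 <- function(code) {
  up <- toupper(code)
  bad <- !is_valid_icd10(up)
  if (any(bad)) {
    stop("not an ICD-10 code: ", paste(utils::head(code[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  substr(up, 1, 3)
}

new_presence_matrix <- function(indicators, is_case) {
  stopifnot(is.matrix(indicators), is.logical(indicators),
            length(is_case) == nrow(indicators),
            !is.null(colnames(indicators)), !is.null(rownames(indicators)))
  structure(list(indicators = indicators, is_case = is_case),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d cases + %d controls x %d clusters\n",
              sum(x$is_case), sum(!x$is_case), ncol(x$indicators)))
  invisible(x)
}

#' Patient-by-cluster presence matrix
#'
#' Indicator is 1 iff the patient has at least one record whose truncated
#' code equals the cluster — repeat visits count once; presence/absence, not
#' visit counts, is the unit of analysis. Records must already be restricted
#' to each patient's pre-index window.
#'
#' @param case_records,control_records Tibbles of claims (`patient_id`,
#'   `icd10_code`) for cases and controls.
#' @param case_ids,control_ids Patient identifiers defining the cohort rows;
#'   default the identifiers present in the records, but must be given
#'   explicitly when some patients have empty record lists (their rows are
#'   all zero).
#' @return An object of class `presence_matrix`: logical matrix `indicators`
#'   (rows = patients, columns = sorted clusters) plus logical `is_case`.
#' @export
presence_matrix <- function(case_records, control_records,
                            case_ids = unique(case_records$patient_id),
                            control_ids = unique(control_records$patient_id)) {
  check_that(length(intersect(case_ids, control_ids)) == 0, "case_ids/control_ids",
             "a patient cannot be both case and control")
  all_ids <- c(case_ids, control_ids)
  recs <- dplyr::bind_rows(case_records[c("patient_id", "icd10_code")],
                           control_records[c("patient_id", "icd10_code")])
  orphan <- setdiff(recs$patient_id, all_ids)
  check_that(length(orphan) == 0, "records",
             paste("records for patients outside the cohort:",
                   paste(utils::head(orphan, 3), collapse = ", ")))
  recs$cluster <- truncate_icd10(recs$icd10_code)
  clusters <- sort(unique(recs$cluster))
  ind <- matrix(FALSE, length(all_ids), length(clusters),
                dimnames = list(all_ids, clusters))
  if (nrow(recs)) {
    ind[cbind(match(recs$patient_id, all_ids),
              match(recs$cluster, clusters))] <- TRUE
  }
  new_presence_matrix(ind, c(rep(TRUE, length(case_ids)),
                             rep(FALSE, length(control_ids))))
}

#' Haldane-Anscombe-corrected odds ratio
#'
#' Adds 1/2 to all four cells of the 2x2 table *unconditionally* (not only
#' when a zero cell occurs) before forming the cross-product ratio, so the
#' estimate is always finite and positive:
#' `((a+1/2)(d+1/2)) / ((b+1/2)(c+1/2))`.
#'
#' @param a,b,c,d Cell counts: exposed cases, unexposed cases, exposed
#'   controls, unexposed controls. Vectorized.
#' @return Positive numeric vector of corrected odds ratios.
#' @export
#' @examples
#' haldane_anscombe_or(4, 163, 0, 501)
haldane_anscombe_or <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  check_that(all(counts >= 0) && all(counts == floor(counts)), "a/b/c/d",
             "cell counts must be nonnegative integers")
  (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))
}

#' Two-sided Fisher exact test
#'
#' Exact hypergeometric test with the point-probability two-sided rule: the
#' p-value is the sum of probabilities, over all tables with the observed
#' margins, whose point probability does not exceed that of the observed
#' table.
#'
#' @param a,b,c,d Cell counts as in [haldane_anscombe_or()]. Vectorized.
#' @return p-values in \[0, 1\].
#' @export
#' @examples
#' fisher_exact_two_sided(3, 164, 0, 501)
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  check_that(all(counts >= 0) && all(counts == floor(counts)), "a/b/c/d",
             "cell counts must be nonnegative integers")
  vapply(seq_len(nrow(counts)), function(i) {
    m <- matrix(counts[i, ], nrow = 2, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
}

# 2x2 cell counts for each cluster column of a presence matrix
cluster_tables <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  n1 <- sum(pm$is_case)
  n0 <- sum(!pm$is_case)
  a <- colSums(pm$indicators[pm$is_case, , drop = FALSE])
  c_ <- colSums(pm$indicators[!pm$is_case, , drop = FALSE])
  tibble::tibble(cluster = colnames(pm$indicators),
                 a = as.integer(a), b = n1 - as.integer(a),
                 c = as.integer(c_), d = n0 - as.integer(c_))
}

#' Screen disease clusters for association with case status
#'
#' For every cluster present in at least one case, computes the 2x2 table of
#' pre-index presence against case status, the Haldane-Anscombe-corrected
#' odds ratio and the two-sided exact Fisher p-value, and flags significance
#' at `alpha`. No multiple-testing correction is applied by default
#' (screening at raw p < alpha); a Benjamini-Hochberg option is available.
#'
#' @param pm A [presence_matrix()].
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Tibble, sorted by cluster code: `cluster`, cell counts
#'   `a`,`b`,`c`,`d`, `odds_ratio`, `p_value`, `significant`.
#' @export
screen_clusters <- function(pm, alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  check_that(alpha > 0 && alpha <= 1, "alpha", "must be in (0, 1]")
  tab <- cluster_tables(pm)
  tab <- tab[tab$a >= 1, ]
  if (nrow(tab) == 0) {
    return(tibble::tibble(cluster = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), odds_ratio = numeric(),
                          p_value = numeric(), significant = logical()))
  }
  tab$odds_ratio <- haldane_anscombe_or(tab$a, tab$b, tab$c, tab$d)
  tab$p_value <- fisher_exact_two_sided(tab$a, tab$b, tab$c, tab$d)
  p_screen <- if (p_adjust == "BH") stats::p.adjust(tab$p_value, "BH") else tab$p_value
  tab$significant <- p_screen < alpha
  dplyr::arrange(tab, .data$cluster)
}

#' Collapse presence-matrix columns into clinical disease groups
#'
#' A patient is exposed to a group iff exposed to at least one member
#' cluster (union, counted once). Clusters listed in `passthrough` are kept
#' as singleton columns.
#'
#' @param pm A [presence_matrix()].
#' @param group_map Named list: group label -> character vector of member
#'   clusters (disjoint; all present in `pm`).
#' @param passthrough Clusters to retain ungrouped.
#' @return A `presence_matrix` whose columns are groups then passthrough
#'   clusters.
#' @export
collapse_groups <- function(pm, group_map, passthrough = character()) {
  stopifnot(inherits(pm, "presence_matrix"))
  validate_group_map(group_map)
  members <- unlist(group_map, use.names = FALSE)
  missing_m <- setdiff(c(members, passthrough), colnames(pm$indicators))
  check_that(length(missing_m) == 0, "group_map",
             paste("clusters absent from the presence matrix:",
                   paste(missing_m, collapse = ", ")))
  check_that(length(intersect(members, passthrough)) == 0, "passthrough",
             "overlaps group members")
  cols <- lapply(group_map, function(m) {
    rowSums(pm$indicators[, m, drop = FALSE]) > 0
  })
  ind <- do.call(cbind, c(cols, lapply(passthrough, function(cl) pm$indicators[, cl])))
  colnames(ind) <- c(names(group_map), passthrough)
  rownames(ind) <- rownames(pm$indicators)
  new_presence_matrix(ind, pm$is_case)
}

#' Regroup screened clusters into clinical disease groups
#'
#' Recomputes the Haldane-Anscombe odds ratio and exact Fisher p-value on
#' the union exposure table of each group; screened clusters not covered by
#' the map pass through unchanged (as singleton groups). This is the step
#' that takes the significant clusters to the clinically regrouped table
#' feeding the network.
#'
#' @param results Tibble from [screen_clusters()] (typically the significant
#'   rows).
#' @param pm The [presence_matrix()] the results were computed from.
#' @param group_map Named list, group label -> member clusters; member
#'   clusters must all appear in `results$cluster`.
#' @param alpha Significance level for the recomputed p-values.
#' @return Tibble: `cluster` (group label), `members` (comma-joined member
#'   codes), `anchor` (first member code, used for chapter coloring), cell
#'   counts, `odds_ratio`, `p_value`, `significant`.
#' @export
regroup <- function(results, pm, group_map, alpha = 0.05) {
  validate_group_map(group_map)
  members <- unlist(group_map, use.names = FALSE)
  outside <- setdiff(members, results$cluster)
  check_that(length(outside) == 0, "group_map",
             paste("codes not among screened clusters:",
                   paste(outside, collapse = ", ")))
  passthrough <- setdiff(results$cluster, members)
  gpm <- collapse_groups(pm, group_map, passthrough)
  tab <- cluster_tables(gpm)
  tab$odds_ratio <- haldane_anscombe_or(tab$a, tab$b, tab$c, tab$d)
  tab$p_value <- fisher_exact_two_sided(tab$a, tab$b, tab$c, tab$d)
  tab$significant <- tab$p_value < alpha
  all_map <- c(group_map, stats::setNames(as.list(passthrough), passthrough))
  tab$members <- unname(vapply(all_map[tab$cluster], paste, character(1),
                               collapse = ","))
  tab$anchor <- unname(vapply(all_map[tab$cluster], `[`, character(1), 1))
  dplyr::arrange(tab[c("cluster", "members", "anchor", "a", "b", "c", "d",
                       "odds_ratio", "p_value", "significant")], .data$anchor)
}

#' Pairwise associations among disease clusters
#'
#' For each unordered pair of clusters, forms the 2x2 table of joint
#' presence/absence over the analysis population (the pooled matched cohort
#' by default; optionally cases only), computes the Haldane-Anscombe odds
#' ratio and exact Fisher p-value, and retains pairs with p < alpha as
#' network edges.
#'
#' @param pm A [presence_matrix()] (possibly group-collapsed via
#'   [collapse_groups()]).
#' @param clusters Columns to consider (default: all).
#' @param alpha Significance level for edge retention.
#' @param population `"all"` (cases + controls pooled, default) or
#'   `"cases"`.
#' @return Tibble of retained edges: `cluster_a`, `cluster_b` (with
#'   `cluster_a < cluster_b`), `odds_ratio`, `p_value`.
#' @export
pairwise_associations <- function(pm, clusters = colnames(pm$indicators),
                                  alpha = 0.05,
                                  population = c("all", "cases")) {
  stopifnot(inherits(pm, "presence_matrix"))
  population <- match.arg(population)
  check_that(length(clusters) >= 2, "clusters", "need at least two clusters")
  missing_c <- setdiff(clusters, colnames(pm$indicators))
  check_that(length(missing_c) == 0, "clusters",
             paste("absent from presence matrix:", paste(missing_c, collapse = ", ")))
  ind <- pm$indicators[, clusters, drop = FALSE]
  if (population == "cases") ind <- ind[pm$is_case, , drop = FALSE]
  n <- nrow(ind)
  pairs <- utils::combn(sort(clusters), 2)
  a <- b <- c_ <- integer(ncol(pairs))
  # joint counts via cross-products of the indicator matrix
  x <- ind * 1L
  cross <- crossprod(x)             # both present
  tot <- colSums(x)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a[k] <- cross[i, j]
    b[k] <- tot[i] - cross[i, j]
    c_[k] <- tot[j] - cross[i, j]
  }
  d <- n - a - b - c_
  out <- tibble::tibble(cluster_a = pairs[1, ], cluster_b = pairs[2, ],
                        odds_ratio = haldane_anscombe_or(a, b, c_, d),
                        p_value = fisher_exact_two_sided(a, b, c_, d))
  out[out$p_value < alpha, ]
}

validate_group_map <- function(group_map) {
  check_that(is.list(group_map) && length(group_map) >= 1 &&
               !is.null(names(group_map)) && all(nzchar(names(group_map))),
             "group_map", "must be a nonempty named list")
  check_that(!anyDuplicated(names(group_map)), "group_map",
             "group labels must be unique")
  members <- unlist(group_map, use.names = FALSE)
  check_that(!anyDuplicated(members), "group_map",
             "groups must be disjoint (a code in at most one group)")
  invisible(TRUE)
}

#' Read a disease-group map from YAML
#'
#' The file maps group labels to member three-character cluster codes:
#' ```yaml
#' "M62/M65/M67": [M62, M65, M67]
#' D64: [D64]
#' ```
#'
#' @param path Path to a YAML file.
#' @return Named list of character vectors, validated (disjoint groups,
#'   unique labels).
#' @export
read_group_map <- function(path) {
  gm <- yaml::read_yaml(path)
  gm <- lapply(gm, as.character)
  validate_group_map(gm)
  bad <- unlist(gm)[!grepl("^[A-Z][0-9]{2}$", unlist(gm))]
  check_that(length(bad) == 0, "group_map",
             paste("not three-character categories:", paste(bad, collapse = ", ")))
  gm
}

#' The 11-group clinical regrouping of the index-disease comorbidity study
#'
#' The published regrouping of the 23 significant clusters into 11 clinical
#' disease groups (muscle/synovium, scoliosis/dorsalgia, trunk and hip
#' injuries, limb injuries, ENT/eye, lower respiratory, skin, plus four
#' singletons). Shipped also as `extdata/lcpd_groups.yaml`.
#'
#' @return Named list of member cluster codes per group label.
#' @export
lcpd_group_map <- function() {
  list(
    "D64" = "D64",
    "H16/H60" = c("H16", "H60"),
    "J41/J45" = c("J41", "J45"),
    "L01/L24" = c("L01", "L24"),
    "M00" = "M00",
    "M41/M54" = c("M41", "M54"),
    "M62/M65/M67" = c("M62", "M65", "M67"),
    "Q65" = "Q65",
    "Q66" = "Q66",
    "S30/S33/S70/S73" = c("S30", "S33", "S70", "S73"),
    "S50/S80/S83/T00" = c("S50", "S80", "S83", "T00")
  )
}

#' Published per-cluster association table of the index-disease study
#'
#' The printed case-control association tables (23 single clusters, and the
#' 11 clinically regrouped rows) of the source case-control study of 167
#' cases and 501 matched controls: exposure counts, reported p-value, odds
#' ratio and network degree. Used as worked-example input for the
#' odds-ratio, Fisher and network stages.
#'
#' @param grouped `FALSE` (default) for the 23 single-cluster rows, `TRUE`
#'   for the 11 grouped rows.
#' @return Tibble with columns `cluster`, `name`, `cases_exposed`,
#'   `controls_exposed`, `cases_total`, `controls_total`, `printed_p`
#'   (character; `"<0.001"` possible), `printed_or`, `printed_or_dp`
#'   (decimals the odds ratio was printed with), `degree`.
#' @export
lcpd_reported_associations <- function(grouped = FALSE) {
  f <- if (grouped) "lcpd_table_grouped.csv" else "lcpd_table_clusters.csv"
  path <- system.file("extdata", f, package = "comorbnet", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$cases_total <- 167L
  out$controls_total <- 501L
  out
}

#' Format an association table for reporting
#'
#' Adds clinical-table formatting: odds ratios rounded half-up to 2
#' decimals, p-values to 3 decimals with `"<0.001"` below that, exposure
#' counts as `n (%)`.
#'
#' @param results Tibble from [screen_clusters()] or [regroup()].
#' @return The input with character columns `or_fmt`, `p_fmt`, `cases_fmt`,
#'   `controls_fmt` appended.
#' @export
format_results <- function(results) {
  results$or_fmt <- sprintf("%.2f", round_half_up(results$odds_ratio, 2))
  results$p_fmt <- format_p(results$p_value)
  n1 <- results$a + results$b
  n0 <- results$c + results$d
  results$cases_fmt <- sprintf("%d (%.1f)", results$a, 100 * results$a / n1)
  results$controls_fmt <- sprintf("%d (%.1f)", results$c, 100 * results$c / n0)
  results
}
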