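# End-to-end orchestration: claims -> cohort -> incidence -> matching ->
# association -> regrouping -> network, with per-stage seeding, stage
# outputs on disk and a reproducible run manifest.

#' Pipeline configuration
#'
#' @param claims_path Path to a delimited claims file ([read_claims()]
#'   schema).
#' @param out_dir Output directory (created if absent).
#' @param cohort A [cohort_spec()].
#' @param match A [match_spec()] (its seed is replaced by a stage seed
#'   derived from `seed`).
#' @param alpha Significance level for every screening step.
#' @param group_map Clinical regrouping: a named list (label -> member
#'   clusters), a path to a YAML file ([read_group_map()]), or `NULL` for no
#'   regrouping. Groups are restricted to the clusters significant in the
#'   run at hand.
#' @param incidence_years Years for the incidence table; `NULL` derives all
#'   full post-washout calendar years of the data.
#' @param incidence_washout_years Washout years for the incidence stage.
#' @param pairwise_population Population for pairwise links: `"all"` or
#'   `"cases"`.
#' @param export_formats Graph formats to write (subset of `"graphml"`,
#'   `"gexf"`).
#' @param index_label Label of the index-disease node.
#' @param seed Run seed; all stage seeds derive from it.
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(claims_path, out_dir,
                            cohort = cohort_spec(),
                            match = match_spec(),
                            alpha = 0.05,
                            group_map = NULL,
                            incidence_years = NULL,
                            incidence_washout_years = 1L,
                            pairwise_population = c("all", "cases"),
                            export_formats = c("graphml", "gexf"),
                            index_label = "LCPD",
                            seed = 1L,
                            verbose = TRUE) {
  check_that(alpha > 0 && alpha <= 1, "alpha", "must be in (0, 1]")
  if (is.character(group_map)) group_map <- read_group_map(group_map)
  if (!is.null(group_map)) validate_group_map(group_map)
  check_that(all(export_formats %in% c("graphml", "gexf")), "export_formats",
             "supported: graphml, gexf")
  structure(list(claims_path = claims_path, out_dir = out_dir,
                 cohort = cohort, match = match, alpha = alpha,
                 group_map = group_map, incidence_years = incidence_years,
                 incidence_washout_years = as.integer(incidence_washout_years),
                 pairwise_population = match.arg(pairwise_population),
                 export_formats = export_formats, index_label = index_label,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the comorbidity-network pipeline
#'
#' Executes cohort construction, incidence, matching, association screening,
#' regrouping and network building in order, writes every stage output under
#' `config$out_dir`, and returns (invisibly) the stage results plus a run
#' manifest (input hash, seed, stage row counts, package version). The same
#' configuration and seed always yield an identical manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with elements `claims`, `cases`, `incidence`,
#'   `sex_rate_p`, `matched`, `associations`, `grouped`, `pairwise`,
#'   `network`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message("[comorbnet] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$cohort
  out <- function(f) file.path(config$out_dir, f)

  say("reading claims: ", config$claims_path)
  cs <- with_stage("read", read_claims(config$claims_path))
  complete <- with_stage("filter_complete", filter_complete(cs))
  say(nrow(complete$patients), " complete patients of ", nrow(cs$patients))

  cases <- with_stage("cohort", find_incident_cases(complete, spec))
  if (nrow(cases) == 0) stop("cohort: no incident cases found", call. = FALSE)
  say(nrow(cases), " incident cases")
  readr::write_csv(cases, out("cases.csv"), progress = FALSE)

  years <- config$incidence_years
  if (is.null(years)) {
    y_first <- as.integer(format(min(complete$claims$visit_date), "%Y"))
    y_last <- as.integer(format(max(complete$claims$visit_date), "%Y"))
    years <- seq(y_first + config$incidence_washout_years, y_last)
  }
  inc <- with_stage("incidence",
    annual_incidence(complete, spec$index_codes, years,
                     washout_years = config$incidence_washout_years,
                     max_age = spec$max_age_years))
  sex_p <- with_stage("incidence", sex_rate_comparison(inc))
  readr::write_csv(inc, out("incidence.csv"), progress = FALSE)

  cand <- with_stage("matching",
    control_candidates(complete, cases, spec,
                       seed = stage_seed(config$seed, "candidates")))
  say(nrow(cand), " control candidates")
  mspec <- config$match
  mspec$seed <- stage_seed(config$seed, "match")
  ps <- with_stage("matching", estimate_propensity(cases, cand))
  mc <- with_stage("matching",
    greedy_match(ps, mspec, observation_end = spec$observation_end))
  readr::write_csv(mc$controls, out("matched_controls.csv"), progress = FALSE)
  readr::write_csv(mc$balance, out("balance.csv"), progress = FALSE)

  case_recs <- with_stage("association",
    extract_pre_diagnosis(complete, cases, spec$index_codes))
  ctrl_cut <- tibble::tibble(patient_id = mc$controls$patient_id,
                             diagnosis_date = mc$controls$pseudo_index_date)
  ctrl_recs <- with_stage("association",
    extract_pre_diagnosis(complete, ctrl_cut, spec$index_codes))
  pm <- with_stage("association",
    presence_matrix(case_recs, ctrl_recs,
                    case_ids = cases$patient_id,
                    control_ids = mc$controls$patient_id))
  res <- with_stage("association", screen_clusters(pm, alpha = config$alpha))
  sig <- res[res$significant, ]
  say(nrow(res), " clusters screened, ", nrow(sig), " significant")
  readr::write_csv(format_results(res), out("associations.csv"), progress = FALSE)

  if (!is.null(config$group_map) && nrow(sig)) {
    gm <- lapply(config$group_map, intersect, sig$cluster)
    gm <- gm[lengths(gm) > 0]
  } else {
    gm <- NULL
  }
  grouped <- if (length(gm)) {
    with_stage("regroup", regroup(sig, pm, gm, alpha = config$alpha))
  } else {
    tibble::tibble(cluster = sig$cluster, members = sig$cluster,
                   anchor = sig$cluster, a = sig$a, b = sig$b, c = sig$c,
                   d = sig$d, odds_ratio = sig$odds_ratio,
                   p_value = sig$p_value, significant = sig$significant)
  }
  gsig <- grouped[grouped$significant, ]
  readr::write_csv(format_results(grouped), out("grouped_associations.csv"),
                   progress = FALSE)
  say(nrow(gsig), " significant groups")

  pw <- if (nrow(gsig) >= 2) {
    gpm <- if (length(gm)) {
      with_stage("pairwise",
        collapse_groups(pm, gm,
                        passthrough = setdiff(sig$cluster,
                                              unlist(gm, use.names = FALSE))))
    } else {
      pm
    }
    with_stage("pairwise",
      pairwise_associations(gpm, clusters = gsig$cluster,
                            alpha = config$alpha,
                            population = config$pairwise_population))
  } else {
    tibble::tibble(cluster_a = character(), cluster_b = character(),
                   odds_ratio = numeric(), p_value = numeric())
  }

  net <- with_stage("network",
    build_network(gsig, pw, index_label = config$index_label))
  for (fmt in config$export_formats) {
    export_network(net, out(paste0("network.", fmt)), fmt)
  }
  export_network(net, out("network_edges.csv"), "edgelist")
  export_network(net, out("network_nodes.csv"), "nodes")

  manifest <- list(
    package = "comorbnet",
    version = as.character(utils::packageVersion("comorbnet")),
    seed = config$seed,
    alpha = config$alpha,
    input = unname(tools::md5sum(config$claims_path)),
    sex_rate_p = sex_p,
    stages = list(
      patients = nrow(cs$patients),
      complete = nrow(complete$patients),
      cases = nrow(cases),
      candidates = nrow(cand),
      controls = nrow(mc$controls),
      clusters_screened = nrow(res),
      clusters_significant = nrow(sig),
      groups_significant = nrow(gsig),
      network_nodes = nrow(net$nodes),
      network_edges = nrow(net$edges)
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done; outputs in ", config$out_dir)
  invisible(list(claims = cs, cases = cases, incidence = inc,
                 sex_rate_p = sex_p, matched = mc, associations = res,
                 grouped = grouped, pairwise = pw, network = net,
                 manifest = manifest))
}
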