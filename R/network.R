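# Comorbidity network: index-disease node plus significant disease
# clusters/groups, degree-sized nodes colored by ICD-10 chapter, edges
# weighted by odds ratio. Exported as GraphML/GEXF plus plain CSV tables.

#' ICD-10 chapter class of a node label
#'
#' Nodes are colored by the first letter of their (anchor) ICD-10 code; a
#' group spanning several codes uses its anchor (first listed member). The
#' index-disease node gets the designated class `"index"`.
#'
#' @param label Node label(s).
#' @param anchor Anchor code per label (defaults to the label itself).
#' @param index_label Label of the index-disease node.
#' @return Character vector: one uppercase letter per cluster/group node,
#'   `"index"` for the index node.
#' @export
#' @examples
#' chapter_of(c("Q65", "LCPD"), index_label = "LCPD")
chapter_of <- function(label, anchor = label, index_label = "LCPD") {
  stopifnot(length(anchor) == length(label))
  out <- character(length(label))
  is_index <- label == index_label
  out[is_index] <- "index"
  code <- toupper(anchor[!is_index])
  bad <- !grepl("^[A-Z][0-9]{2}", code)
  if (any(bad)) {
    stop("node label(s) not anchored by an ICD-10 code: ",
         paste(utils::head(label[!is_index][bad], 5), collapse = ", "),
         call. = FALSE)
  }
  out[!is_index] <- substr(code, 1, 1)
  out
}

#' Build the comorbidity network
#'
#' Nodes are the index disease plus the significant clusters/groups; edges
#' are the index-to-cluster link for every significant cluster (weighted by
#' its case-control odds ratio) plus the screened pairwise cluster-cluster
#' links. Node degree is computed from the final edge set and is the node
#' size attribute.
#'
#' @param index_results Tibble of significant cluster/group associations
#'   with the index disease ([screen_clusters()] or [regroup()] output;
#'   needs `cluster`, `odds_ratio`, `p_value`, optionally `anchor`).
#' @param pairwise_edges Tibble from [pairwise_associations()] (needs
#'   `cluster_a`, `cluster_b`, `odds_ratio`, `p_value`); may be empty.
#' @param index_label Label of the index-disease node.
#' @return An object of class `comorbidity_network`: list of tibbles `nodes`
#'   (`label`, `chapter`, `degree`) and `edges` (`from`, `to`, `or`, `p`).
#' @export
build_network <- function(index_results,
                          pairwise_edges = NULL,
                          index_label = "LCPD") {
  stopifnot(all(c("cluster", "odds_ratio", "p_value") %in% names(index_results)))
  check_that(!anyDuplicated(index_results$cluster), "index_results",
             "duplicate cluster labels")
  check_that(!index_label %in% index_results$cluster, "index_label",
             "collides with a cluster label")
  anchor <- if ("anchor" %in% names(index_results)) {
    index_results$anchor
  } else {
    index_results$cluster
  }
  edges <- tibble::tibble(from = index_label,
                          to = index_results$cluster,
                          or = index_results$odds_ratio,
                          p = index_results$p_value)
  if (!is.null(pairwise_edges) && nrow(pairwise_edges)) {
    labels <- c(index_label, index_results$cluster)
    unknown <- setdiff(c(pairwise_edges$cluster_a, pairwise_edges$cluster_b), labels)
    if (length(unknown)) {
      stop("pairwise edge references unknown node(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    pe <- tibble::tibble(from = pmin(pairwise_edges$cluster_a, pairwise_edges$cluster_b),
                         to = pmax(pairwise_edges$cluster_a, pairwise_edges$cluster_b),
                         or = pairwise_edges$odds_ratio,
                         p = pairwise_edges$p_value)
    check_that(all(pe$from != pe$to), "pairwise_edges", "self-loops not allowed")
    check_that(!anyDuplicated(pe[c("from", "to")]), "pairwise_edges",
               "duplicate unordered edges")
    edges <- dplyr::bind_rows(edges, pe)
  }
  check_that(all(edges$or > 0), "edges", "edge weights must be positive")
  nodes <- tibble::tibble(
    label = c(index_label, index_results$cluster),
    chapter = chapter_of(c(index_label, index_results$cluster),
                         anchor = c(index_label, anchor),
                         index_label = index_label)
  )
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$label))
  nodes$degree <- as.integer(deg[nodes$label])
  structure(list(nodes = nodes, edges = edges, index_label = index_label),
            class = "comorbidity_network")
}

#' @export
print.comorbidity_network <- function(x, ...) {
  cat(sprintf("<comorbidity_network> %d nodes, %d edges; index node \"%s\" degree %d\n",
              nrow(x$nodes), nrow(x$edges), x$index_label,
              x$nodes$degree[x$nodes$label == x$index_label]))
  invisible(x)
}

#' Convert a comorbidity network to igraph
#'
#' @param network A [build_network()] result.
#' @return An undirected `igraph` graph with node attributes `chapter`,
#'   `degree` and edge attributes `weight` (odds ratio) and `p`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "comorbidity_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$from, to = network$edges$to,
                   weight = network$edges$or, p = network$edges$p),
    directed = FALSE,
    vertices = as.data.frame(network$nodes)
  )
  g
}

#' Export a comorbidity network
#'
#' Writes the graph with node attributes (`degree`, `chapter`) and edge
#' attributes (`weight` = odds ratio, `p`) in a format readable by standard
#' graph tools: `"graphml"`, `"gexf"` (GEXF 1.2), `"edgelist"` (CSV
#' `source,target,or,p`) or `"nodes"` (CSV `label,degree,chapter`).
#'
#' @param network A [build_network()] result.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"gexf"`, `"edgelist"`, `"nodes"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("graphml", "gexf", "edgelist", "nodes")) {
  stopifnot(inherits(network, "comorbidity_network"))
  supported <- c("graphml", "gexf", "edgelist", "nodes")
  if (length(format) == 1 && !format %in% supported) {
    stop("unknown format \"", format, "\"; supported: ",
         paste(supported, collapse = ", "), call. = FALSE)
  }
  format <- match.arg(format)
  switch(format,
    graphml = igraph::write_graph(as_igraph(network), path, format = "graphml"),
    gexf = write_gexf(network, path),
    edgelist = readr::write_csv(
      tibble::tibble(source = network$edges$from, target = network$edges$to,
                     or = network$edges$or, p = network$edges$p),
      path, progress = FALSE),
    nodes = readr::write_csv(network$nodes, path, progress = FALSE)
  )
  invisible(path)
}

# Minimal GEXF 1.2 writer (undirected, static graph, node/edge attvalues).
write_gexf <- function(network, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected",
                               mode = "static")
  natt <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(natt, "attribute", id = "0", title = "degree", type = "integer")
  xml2::xml_add_child(natt, "attribute", id = "1", title = "chapter", type = "string")
  eatt <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eatt, "attribute", id = "0", title = "p", type = "double")
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(network$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = network$nodes$label[i],
                              label = network$nodes$label[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = as.character(network$nodes$degree[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = network$nodes$chapter[i])
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(network$edges))) {
    ed <- xml2::xml_add_child(edges, "edge",
                              id = as.character(i - 1L),
                              source = network$edges$from[i],
                              target = network$edges$to[i],
                              weight = format(network$edges$or[i], digits = 10))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = format(network$edges$p[i], digits = 10))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
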