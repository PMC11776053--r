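# Map serialization -----------------------------------------------------------

#' Write a perturbation map as GraphML
#'
#' Nodes carry `name`, `smiles` and `role`; edges carry `score` and the
#' `optimal` flag (as 0/1). The file round-trips through
#' [read_map_graphml()].
#'
#' @param map A `perturbation_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_map_graphml <- function(map, path) {
  g <- map$graph
  if (is.null(igraph::vertex_attr(g, "role"))) igraph::V(g)$role <- "intermediate"
  if (is.null(igraph::vertex_attr(g, "smiles"))) igraph::V(g)$smiles <- ""
  if (is.null(igraph::edge_attr(g, "optimal"))) igraph::E(g)$optimal <- FALSE
  igraph::E(g)$optimal <- as.integer(igraph::E(g)$optimal)
  g$endpoint_a <- if (!is.null(map$endpoints)) map$endpoints[1L] else ""
  g$endpoint_b <- if (!is.null(map$endpoints)) map$endpoints[2L] else ""
  g$optimal_path <- paste(map$optimal_path, collapse = ",")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a perturbation map from GraphML
#'
#' @param path File written by [write_map_graphml()].
#' @return A `perturbation_map` (without construction parameters).
#' @export
read_map_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  igraph::E(g)$optimal <- as.logical(as.integer(igraph::E(g)$optimal))
  ep <- c(igraph::graph_attr(g, "endpoint_a"), igraph::graph_attr(g, "endpoint_b"))
  if (!nzchar(ep[1L])) ep <- NULL
  op <- igraph::graph_attr(g, "optimal_path")
  op <- if (nzchar(op)) strsplit(op, ",", fixed = TRUE)[[1]] else NULL
  new_perturbation_map(g, endpoints = ep, optimal_path = op, params = NULL)
}

#' Write a perturbation map as a flat CSV edge list
#'
#' Columns: `u`, `v`, `score`, `optimal`, plus the endpoint SMILES where
#' known. Round-trips through [read_map_csv()] (topology and scores only).
#'
#' @param map A `perturbation_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  g <- map$graph
  ed <- .edge_df(g)
  ed$optimal <- if (is.null(igraph::edge_attr(g, "optimal")))
    FALSE else igraph::E(g)$optimal
  sm <- igraph::vertex_attr(g, "smiles")
  if (!is.null(sm)) {
    names(sm) <- igraph::V(g)$name
    ed$smiles_u <- unname(sm[ed$u])
    ed$smiles_v <- unname(sm[ed$v])
  }
  utils::write.csv(ed, path, row.names = FALSE)
  invisible(path)
}

#' Read a perturbation map from a CSV edge list
#' @param path File written by [write_map_csv()].
#' @return A `perturbation_map`.
#' @export
read_map_csv <- function(path) {
  ed <- utils::read.csv(path, stringsAsFactors = FALSE)
  g <- make_scored_graph(edges = ed[, c("u", "v", "score")])
  igraph::E(g)$optimal <- as.logical(ed$optimal)
  if ("smiles_u" %in% names(ed)) {
    sm <- c(stats::setNames(ed$smiles_u, ed$u), stats::setNames(ed$smiles_v, ed$v))
    igraph::V(g)$smiles <- unname(sm[igraph::V(g)$name])
  }
  new_perturbation_map(g, endpoints = NULL, optimal_path = NULL, params = NULL)
}

#' Write a score matrix as CSV
#' @param m Matrix from [score_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
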