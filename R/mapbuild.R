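# Perturbation map construction ----------------------------------------------
#
# Starting from the pruned candidate graph, edges are removed worst-score
# first; a removal is kept only while (1) every optimal link is retained and
# (2) every optimal link still lies on a thermodynamic cycle of at most
# MAX_CYCLE edges (checked only for links where the starting graph offered
# such a cycle at all - if none ever existed the link is flagged rather than
# silently passed). Finally the graph is restricted to the corridor of
# simple A-B paths within MAX_SUBGRAPH_DIST, which drops intermediates the
# map never references.

edge_key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\x1f")

# does edge (u,v) lie on a cycle of <= k edges? equivalently: an alternative
# u-v path of <= k-1 edges exists after removing the edge
.on_small_cycle <- function(g, u, v, k) {
  e <- igraph::get_edge_ids(g, c(u, v))
  if (e == 0) return(FALSE)
  g2 <- igraph::delete_edges(g, e)
  d <- igraph::distances(g2, v = u, to = v)[1L, 1L]
  is.finite(d) && d + 1 <= k
}

.edge_df <- function(g) {
  el <- igraph::as_edgelist(g)
  data.frame(u = el[, 1L], v = el[, 2L], score = igraph::E(g)$score,
             stringsAsFactors = FALSE)
}

new_perturbation_map <- function(graph, endpoints, optimal_path, params,
                                 constraint_report = NULL, warnings = character(0),
                                 members = NULL) {
  structure(list(graph = graph, endpoints = endpoints,
                 optimal_path = optimal_path, params = params,
                 constraint_report = constraint_report,
                 warnings = warnings, members = members),
            class = "perturbation_map")
}

#' @export
print.perturbation_map <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<perturbation_map> %d nodes, %d links\n",
              igraph::vcount(g), igraph::ecount(g)))
  if (!is.null(x$endpoints))
    cat("  endpoints:", paste(x$endpoints, collapse = " / "), "\n")
  if (!is.null(x$optimal_path))
    cat("  optimal path:", paste(x$optimal_path, collapse = " - "), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

.as_scored_graph <- function(x, beta = 0.1, timeout = 10) {
  if (inherits(x, "perturbation_map")) return(x$graph)
  candidate_graph(x, min_score = 0, beta = beta, timeout = timeout)
}

.opt_edge_pairs <- function(optimal_path) {
  ids <- if (inherits(optimal_path, "xform_path")) optimal_path$node_ids else optimal_path
  cbind(ids[-length(ids)], ids[-1L])
}

#' Build a pair perturbation map
#'
#' @param x A `generation_result` or an igraph with a `score` edge attribute
#'   covering the candidate compounds.
#' @param optimal The optimal intermediate path (`xform_path`) between the
#'   two input ligands, computed over the same candidates.
#' @param params A [run_config()]; `prune_threshold`, `max_cycle` and
#'   `max_subgraph_dist` are used here.
#' @return A `perturbation_map`. When no cycle of admissible size exists for
#'   some optimal link even on the full pruned graph, the map is returned
#'   with that link flagged infeasible in `constraint_report` and a warning,
#'   never silently.
#' @export
build_pair_map <- function(x, optimal, params = run_config()) {
  stopifnot(inherits(optimal, "xform_path"))
  g <- .as_scored_graph(x, beta = params$beta, timeout = params$mcs_timeout)
  opt <- .opt_edge_pairs(optimal)
  a_id <- optimal$node_ids[1L]
  b_id <- optimal$node_ids[length(optimal$node_ids)]

  # prune, but never the optimal links
  okeys <- edge_key(opt[, 1L], opt[, 2L])
  ek <- edge_key(igraph::as_edgelist(g)[, 1L], igraph::as_edgelist(g)[, 2L])
  drop <- which(igraph::E(g)$score < params$prune_threshold & !(ek %in% okeys))
  g <- igraph::delete_edges(g, drop)
  if (!all(okeys %in% edge_key(igraph::as_edgelist(g)[, 1L],
                               igraph::as_edgelist(g)[, 2L])))
    stop("optimal path links missing from the candidate graph")

  feas0 <- vapply(seq_len(nrow(opt)), function(k)
    .on_small_cycle(g, opt[k, 1L], opt[k, 2L], params$max_cycle), TRUE)

  constraints_ok <- function(gr) {
    for (k in seq_len(nrow(opt))) {
      u <- opt[k, 1L]; v <- opt[k, 2L]
      if (!all(c(u, v) %in% igraph::V(gr)$name)) return(FALSE)
      if (igraph::get_edge_ids(gr, c(u, v)) == 0) return(FALSE)
      if (feas0[k] && !.on_small_cycle(gr, u, v, params$max_cycle)) return(FALSE)
    }
    TRUE
  }

  # one worst-first pass suffices: deleting edges never creates cycles, so a
  # removal that was rejected once can never become admissible later
  ed <- .edge_df(g)
  ed$key <- edge_key(ed$u, ed$v)
  ed <- ed[!(ed$key %in% okeys), , drop = FALSE]
  ed <- ed[order(ed$score, pmin(ed$u, ed$v), pmax(ed$u, ed$v)), , drop = FALSE]
  for (r in seq_len(nrow(ed))) {
    if (!all(c(ed$u[r], ed$v[r]) %in% igraph::V(g)$name)) next
    eid <- igraph::get_edge_ids(g, c(ed$u[r], ed$v[r]))
    if (eid == 0) next   # already gone via an earlier corridor extraction
    g2 <- igraph::delete_edges(g, eid)
    if (params$subgraph_mode == "during") {
      g2 <- tryCatch(.extract_corridor(g2, a_id, b_id, params$max_subgraph_dist),
                     error = function(e) NULL)
      if (is.null(g2)) next
    }
    if (constraints_ok(g2)) g <- g2
  }

  # finalization: restrict to the A-B corridor unless that breaks constraints
  gs <- tryCatch(.extract_corridor(g, a_id, b_id, params$max_subgraph_dist),
                 error = function(e) NULL)
  if (!is.null(gs) && constraints_ok(gs)) g <- gs
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0 &
                                                 !(igraph::V(g)$name %in% c(a_id, b_id))])
  g <- .mark_optimal_edges(g, opt)

  map <- new_perturbation_map(g, c(a_id, b_id), optimal$node_ids, params)
  map$constraint_report <- check_constraints(map, max_cycle = params$max_cycle,
                                             feasible = feas0)
  if (any(!map$constraint_report$cycle_ok))
    map$warnings <- c(map$warnings, sprintf(
      "no cycle of size <= %d available for optimal link(s): %s",
      params$max_cycle,
      paste(with(map$constraint_report,
                 paste(u[!cycle_ok], v[!cycle_ok], sep = "-")), collapse = ", ")))
  map
}

.mark_optimal_edges <- function(g, opt) {
  ek <- edge_key(igraph::as_edgelist(g)[, 1L], igraph::as_edgelist(g)[, 2L])
  igraph::E(g)$optimal <- ek %in% edge_key(opt[, 1L], opt[, 2L])
  g
}

.extract_corridor <- function(g, a_id, b_id, max_subgraph_dist) {
  if (!all(c(a_id, b_id) %in% igraph::V(g)$name))
    stop("endpoints missing from graph")
  d <- igraph::distances(g, v = a_id, to = b_id)[1L, 1L]
  if (!is.finite(d)) stop("endpoints are disconnected")
  vp <- igraph::all_simple_paths(g, a_id, b_id, cutoff = max_subgraph_dist)
  keep <- unique(unlist(lapply(vp, as.integer)))
  if (!length(keep)) stop("no A-B path within max_subgraph_dist")
  igraph::induced_subgraph(g, sort(keep))
}

#' Extract the A-B corridor subgraph of a map
#'
#' Keeps exactly the nodes lying on some simple path between the two input
#' ligands of at most `max_subgraph_dist` edges (with induced edges). The
#' operation is idempotent.
#'
#' @param map A `perturbation_map` (or scored igraph plus `endpoints`).
#' @param max_subgraph_dist Maximum path length in edges.
#' @param endpoints Required when `map` is a bare igraph.
#' @return Same type as `map`.
#' @export
extract_ab_subgraph <- function(map, max_subgraph_dist = 4, endpoints = NULL) {
  if (inherits(map, "perturbation_map")) {
    ep <- map$endpoints
    map$graph <- .extract_corridor(map$graph, ep[1L], ep[2L], max_subgraph_dist)
    return(map)
  }
  stopifnot(igraph::is_igraph(map), length(endpoints) == 2L)
  .extract_corridor(map, endpoints[1L], endpoints[2L], max_subgraph_dist)
}

#' Check the optimal-link constraints of a map
#'
#' For each optimal link: is it present, and does it lie on a cycle of at
#' most `max_cycle` edges?
#'
#' @param map A `perturbation_map`.
#' @param optimal_links Two-column matrix of link endpoints; defaults to the
#'   consecutive pairs of the map's optimal path.
#' @param max_cycle Cycle-size threshold.
#' @param feasible Optional logical vector: whether a small cycle existed on
#'   the full pruned graph (reported as-is for context).
#' @return `data.frame` with columns `u`, `v`, `present`, `cycle_ok`,
#'   `feasible`; attribute `pass` is `TRUE` when all present links with a
#'   feasible cycle satisfy the constraint.
#' @export
check_constraints <- function(map, optimal_links = NULL, max_cycle = 4,
                              feasible = NULL) {
  g <- if (inherits(map, "perturbation_map")) map$graph else map
  if (is.null(optimal_links)) {
    stopifnot(inherits(map, "perturbation_map"), !is.null(map$optimal_path))
    optimal_links <- .opt_edge_pairs(map$optimal_path)
  }
  n <- nrow(optimal_links)
  if (is.null(feasible)) feasible <- rep(TRUE, n)
  present <- cycle_ok <- logical(n)
  for (k in seq_len(n)) {
    u <- optimal_links[k, 1L]; v <- optimal_links[k, 2L]
    present[k] <- all(c(u, v) %in% igraph::V(g)$name) &&
      igraph::get_edge_ids(g, c(u, v)) != 0
    cycle_ok[k] <- present[k] && .on_small_cycle(g, u, v, max_cycle)
  }
  out <- data.frame(u = optimal_links[, 1L], v = optimal_links[, 2L],
                    present = present, cycle_ok = cycle_ok,
                    feasible = feasible, stringsAsFactors = FALSE)
  attr(out, "pass") <- all(present) && all(cycle_ok[feasible])
  out
}

#' Bridges of a perturbation map
#'
#' A bridge is a link not included in any thermodynamic cycle (a cut edge);
#' across a bridge no cycle-closure error checking is possible.
#'
#' @param map A `perturbation_map` or scored igraph.
#' @return `data.frame` with columns `u`, `v`, `score`.
#' @export
find_bridges <- function(map) {
  g <- if (inherits(map, "perturbation_map")) map$graph else map
  br <- as.integer(igraph::bridges(g))
  el <- igraph::as_edgelist(g)
  data.frame(u = el[br, 1L], v = el[br, 2L],
             score = igraph::E(g)$score[br], stringsAsFactors = FALSE)
}

#' Summary statistics of a perturbation map
#'
#' @param map A `perturbation_map`.
#' @return List with `worst_link_score`, `ab_distance` (graph distance in
#'   links between the input compounds), `n_intermediates`, `n_links`, and
#'   `optimal_path_has_bridge`.
#' @export
map_statistics <- function(map) {
  stopifnot(inherits(map, "perturbation_map"))
  g <- map$graph
  ep <- map$endpoints
  roles <- igraph::vertex_attr(g, "role")
  n_inter <- if (!is.null(roles)) sum(roles == "intermediate")
             else igraph::vcount(g) - length(unique(ep))
  br <- find_bridges(map)
  opt <- .opt_edge_pairs(map$optimal_path)
  has_bridge <- nrow(br) > 0 &&
    any(edge_key(opt[, 1L], opt[, 2L]) %in% edge_key(br$u, br$v))
  list(worst_link_score = min(igraph::E(g)$score),
       ab_distance = unname(igraph::distances(g, v = ep[1L], to = ep[2L])[1L, 1L]),
       n_intermediates = n_inter,
       n_links = igraph::ecount(g),
       optimal_path_has_bridge = has_bridge)
}
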