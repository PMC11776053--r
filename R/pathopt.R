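# Optimal intermediate path --------------------------------------------------
#
# The candidate compounds form a scored graph (link-score edges). The optimal
# intermediate path between the two input ligands is the simple path that
# maximizes the path score among paths whose every link score reaches
# MIN_SCORE and whose length does not exceed MAX_DIST edges. The candidate
# graphs are small, so the search is an exhaustive depth-bounded enumeration
# of simple paths, which doubles as its own certificate of optimality.

#' Build the scored candidate graph
#'
#' @param x A `generation_result`, a precomputed score matrix (symmetric,
#'   unit diagonal, dimnames = compound ids), or an igraph whose edges carry
#'   a `score` attribute.
#' @param min_score Minimum link score for an edge to be included; `0` keeps
#'   the complete graph.
#' @param beta,timeout Passed to [score_matrix()] when `x` is a
#'   `generation_result`.
#' @return An igraph with vertex attributes `name`, `role`, `smiles` (where
#'   known) and edge attribute `score`.
#' @export
candidate_graph <- function(x, min_score = 0, beta = 0.1, timeout = 10) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (is.null(igraph::edge_attr(g, "score")))
      stop("graph edges must carry a 'score' attribute")
  } else if (inherits(x, "generation_result")) {
    m <- score_matrix(x$records, beta = beta, timeout = timeout)
    g <- .graph_from_score_matrix(m)
    igraph::V(g)$role <- vapply(x$records[igraph::V(g)$name], function(r) r$role, "")
    igraph::V(g)$smiles <- vapply(x$records[igraph::V(g)$name], function(r) r$key, "")
  } else if (is.matrix(x)) {
    g <- .graph_from_score_matrix(x)
  } else {
    stop("cannot build a candidate graph from this object")
  }
  igraph::delete_edges(g, igraph::E(g)[igraph::E(g)$score < min_score])
}

.graph_from_score_matrix <- function(m) {
  stopifnot(isSymmetric(unname(m)), !is.null(rownames(m)))
  ids <- rownames(m)
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  idx <- which(upper.tri(m), arr.ind = TRUE)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, t(cbind(ids[idx[, 1L]], ids[idx[, 2L]])))
    igraph::E(g)$score <- m[idx]
  }
  g
}

edge_score_between <- function(g, u, v) {
  igraph::E(g)[igraph::`%--%`(u, v)]$score[1L]
}

path_edge_scores <- function(g, ids) {
  vapply(seq_len(length(ids) - 1L),
         function(k) edge_score_between(g, ids[k], ids[k + 1L]), 0)
}

.new_xform_path <- function(ids, scores, fallback = FALSE) {
  ps <- path_score(scores)
  structure(list(node_ids = ids, edge_scores = scores, score = ps$value,
                 worst_link = min(scores), length = length(scores),
                 fallback = fallback),
            class = "xform_path")
}

#' @export
print.xform_path <- function(x, ...) {
  cat(sprintf("<xform_path> %s  (score %.4f, worst link %.4f, length %d)%s\n",
              paste(x$node_ids, collapse = " - "), x$score, x$worst_link,
              x$length, if (x$fallback) " [fallback: min_score not satisfiable]" else ""))
  invisible(x)
}

# rank candidate paths: best path score, then shortest, then best worst link,
# then lexicographically smallest id sequence (determinism)
.select_best_path <- function(paths, by = c("score", "worst")) {
  by <- match.arg(by)
  keyfun <- function(p) paste(p$node_ids, collapse = "\x1f")
  ord <- order(
    if (by == "score") -vapply(paths, `[[`, 0, "score") else -vapply(paths, `[[`, 0, "worst_link"),
    vapply(paths, `[[`, 0L, "length"),
    if (by == "score") -vapply(paths, `[[`, 0, "worst_link") else -vapply(paths, `[[`, 0, "score"),
    vapply(paths, keyfun, ""))
  paths[[ord[1L]]]
}

#' Find the optimal intermediate path between the two input ligands
#'
#' Enumerates every simple path of at most `max_dist` edges in the candidate
#' graph restricted to links with score at least `min_score`, and returns
#' the one with the highest path score. Ties are broken by shorter length,
#' then higher worst link, then lexicographic node ids. When no qualifying
#' path exists, an error of class `alchemap_no_path` is raised; it carries
#' (as `$fallback_path`) the best-effort path maximizing the worst link
#' within `max_dist` while ignoring `min_score`, flagged as a fallback.
#'
#' @param graph Scored candidate graph (see [candidate_graph()]).
#' @param a_id,b_id Vertex names of the two input ligands (must differ).
#' @param min_score Minimum admissible link score for path edges.
#' @param max_dist Maximum path length in edges.
#' @return An object of class `xform_path`.
#' @export
find_optimal_path <- function(graph, a_id, b_id, min_score = 0.5, max_dist = 3) {
  stopifnot(igraph::is_igraph(graph), max_dist >= 1)
  if (identical(a_id, b_id))
    stop("the two endpoints must be different compounds")
  vn <- igraph::V(graph)$name
  if (!all(c(a_id, b_id) %in% vn))
    stop("endpoints not present in the candidate graph")
  gf <- igraph::delete_edges(graph, igraph::E(graph)[igraph::E(graph)$score < min_score])
  mk <- function(g, vpaths) lapply(vpaths, function(vp) {
    ids <- igraph::V(g)$name[as.integer(vp)]
    .new_xform_path(ids, path_edge_scores(g, ids))
  })
  cands <- mk(gf, igraph::all_simple_paths(gf, a_id, b_id, cutoff = max_dist))
  if (length(cands)) return(.select_best_path(cands, by = "score"))

  # infeasible under min_score: report the widest path within max_dist instead
  all_cands <- mk(graph, igraph::all_simple_paths(graph, a_id, b_id, cutoff = max_dist))
  fb <- NULL
  if (length(all_cands)) {
    fb <- .select_best_path(all_cands, by = "worst")
    fb$fallback <- TRUE
  }
  cond <- structure(
    class = c("alchemap_no_path", "error", "condition"),
    list(message = sprintf(
           "no path from %s to %s with all link scores >= %g within %d edges%s",
           a_id, b_id, min_score, max_dist,
           if (is.null(fb)) " (endpoints not connected within max_dist)"
           else sprintf("; best-effort worst link is %.4f", fb$worst_link)),
         call = sys.call(-1), fallback_path = fb))
  stop(cond)
}

#' Summary statistics of a transformation path
#'
#' @param path An `xform_path`.
#' @return List with `worst_link` (minimum edge score), `length` (edge
#'   count) and `score` (path score) - the three quantities used to compare
#'   planned paths.
#' @export
path_stats <- function(path) {
  stopifnot(inherits(path, "xform_path"))
  list(worst_link = path$worst_link, length = path$length, score = path$score)
}
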