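# Congeneric-series maps ------------------------------------------------------
#
# Series mode starts from a Lomap-style map over the series members (worst-
# first edge removal under connectivity, distance, and cycle-cover
# constraints). Member-member links scoring below the series threshold are
# "bad": for each, the pair machinery generates intermediates and the optimal
# intermediate path, whose compounds are injected (deduplicated by canonical
# key) into the compound set. The map is then rebuilt incrementally - only
# edges between new intermediates and existing nodes are added - with the
# constraints relaxed for intermediates (no connectivity, distance, or
# cyclicity requirements on them), which lets the worst-first pass drop the
# bad member-member edge in favor of the injected path. Intermediates that
# end up disconnected from the main graph or as leaves are pruned to a
# fixpoint, and the whole cycle repeats until no bad member-member edge
# remains or the iteration cap is hit.

.member_ids <- function(state) names(which(vapply(state$records, function(r)
  r$role == "series_member", TRUE)))

.series_edge_df <- function(g, records) {
  ed <- .edge_df(g)
  is_member <- function(id) vapply(records[id], function(r) r$role == "series_member", TRUE)
  ed$member_edge <- is_member(ed$u) & is_member(ed$v)
  ed
}

# worst-first constrained removal shared by the base build and the rebuilds
.lomap_style_reduce <- function(g, members, params, check_members_only = FALSE) {
  feas0 <- new.env(parent = emptyenv())
  ek_all <- edge_key(igraph::as_edgelist(g)[, 1L], igraph::as_edgelist(g)[, 2L])
  el <- igraph::as_edgelist(g)
  for (k in seq_len(igraph::ecount(g)))
    assign(ek_all[k], .on_small_cycle(g, el[k, 1L], el[k, 2L], params$max_cycle),
           envir = feas0)

  constrained_edge <- function(u, v) {
    !check_members_only || (u %in% members && v %in% members)
  }
  ok <- function(gr) {
    # connectivity + pairwise distance among members (paths may run through
    # intermediates); cycle cover for constrained edges where feasible
    d <- igraph::distances(gr, v = members, to = members)
    if (any(!is.finite(d)) || any(d > params$base_dmax)) return(FALSE)
    el2 <- igraph::as_edgelist(gr)
    for (k in seq_len(igraph::ecount(gr))) {
      u <- el2[k, 1L]; v <- el2[k, 2L]
      if (!constrained_edge(u, v)) next
      key <- edge_key(u, v)
      if (isTRUE(feas0[[key]]) && !.on_small_cycle(gr, u, v, params$max_cycle))
        return(FALSE)
    }
    TRUE
  }

  ed <- .edge_df(g)
  ed <- ed[order(ed$score, pmin(ed$u, ed$v), pmax(ed$u, ed$v)), , drop = FALSE]
  for (r in seq_len(nrow(ed))) {
    eid <- igraph::get_edge_ids(g, c(ed$u[r], ed$v[r]))
    if (eid == 0) next
    g2 <- igraph::delete_edges(g, eid)
    if (ok(g2)) g <- g2
  }
  g
}

#' Build the Lomap-style base map over series members
#'
#' All pairs are scored; edges are then removed worst-first while the map
#' stays connected, every member remains within `base_dmax` links of every
#' other, and each retained edge keeps a cycle of at most `max_cycle` edges
#' whenever the full graph offered one.
#'
#' @param members Named list of `compound_record`s (role `series_member`) or
#'   `molgraph`s.
#' @param params A [run_config()].
#' @return A `perturbation_map` with `members` set and `endpoints = NULL`.
#' @export
build_base_map <- function(members, params = run_config()) {
  if (length(members) < 2L)
    stop("a series needs at least two members")
  ids <- names(members)
  if (is.null(ids)) ids <- sprintf("M%02d", seq_along(members))
  records <- list()
  for (k in seq_along(members)) {
    m <- members[[k]]
    records[[ids[k]]] <- if (inherits(m, "compound_record")) m else
      compound_record(m, ids[k], "series_member")
    records[[ids[k]]]$role <- "series_member"
  }
  charges <- vapply(records, function(r) net_charge(r$mol), 0L)
  if (length(unique(charges)) != 1L)
    stop("series members must share one net charge")

  m <- score_matrix(records, beta = params$beta, timeout = params$mcs_timeout)
  g <- .graph_from_score_matrix(m)
  igraph::V(g)$role <- "series_member"
  igraph::V(g)$smiles <- vapply(records[igraph::V(g)$name], function(r) r$key, "")
  g <- .lomap_style_reduce(g, ids, params)
  map <- new_perturbation_map(g, endpoints = NULL, optimal_path = NULL,
                              params = params, members = ids)
  attr(map, "records") <- records
  map
}

new_series_state <- function(map, records, params) {
  structure(list(map = map, records = records, params = params,
                 injected = character(0), failed_edges = character(0),
                 iteration = 0L, log = list()),
            class = "series_state")
}

.bad_member_edges <- function(state) {
  ed <- .series_edge_df(state$map$graph, state$records)
  ed <- ed[ed$member_edge & ed$score < state$params$series_threshold, , drop = FALSE]
  ed[!(edge_key(ed$u, ed$v) %in% state$failed_edges), , drop = FALSE]
}

#' Inject optimal intermediate paths for sub-threshold series links
#'
#' For every member-member link below the series threshold, generates
#' intermediates for that pair, finds its optimal intermediate path, and
#' adds the path's compounds (deduplicated against all known compounds) to
#' the set; then rebuilds the map incrementally with intermediate-relaxed
#' constraints. Pairs for which no qualifying path exists keep their direct
#' link and are excluded from later rounds.
#'
#' @param state A `series_state` (from [build_series_map()]'s loop or
#'   constructed around a base map).
#' @param threshold Series link-score threshold; defaults to the state's.
#' @return The updated `series_state`.
#' @export
inject_intermediates <- function(state, threshold = NULL) {
  params <- state$params
  if (!is.null(threshold)) params$series_threshold <- threshold
  bad <- .bad_member_edges(state)
  if (!nrow(bad)) return(state)
  new_recs <- list()
  for (r in seq_len(nrow(bad))) {
    u <- bad$u[r]; v <- bad$v[r]
    gen <- exhaustive_generate(state$records[[u]], state$records[[v]],
                               timeout = params$mcs_timeout)
    path <- tryCatch({
      cg <- candidate_graph(gen, min_score = 0, beta = params$beta,
                            timeout = params$mcs_timeout)
      find_optimal_path(cg, gen$a_id, gen$b_id,
                        min_score = params$min_score, max_dist = params$max_dist)
    }, alchemap_no_path = function(e) NULL, error = function(e) NULL)
    if (is.null(path)) {
      state$failed_edges <- c(state$failed_edges, edge_key(u, v))
      state$log <- c(state$log, sprintf(
        "no qualifying intermediate path for %s-%s; direct link kept", u, v))
      next
    }
    inner <- setdiff(path$node_ids, c(gen$a_id, gen$b_id))
    for (id in inner) {
      rec <- gen$records[[id]]
      known <- vapply(c(state$records, new_recs), function(x) x$key, "")
      if (rec$key %in% known) next   # excluding duplicates
      nid <- sprintf("X%03d", length(state$injected) + length(new_recs) + 1L)
      rec$id <- nid
      new_recs[[nid]] <- rec
    }
  }
  if (length(new_recs)) {
    state <- .series_add_intermediates(state, new_recs)
    state$injected <- c(state$injected, names(new_recs))
  }
  state$map$graph <- .lomap_style_reduce(state$map$graph, .member_ids(state),
                                         params, check_members_only = TRUE)
  state
}

# incremental rebuild: add the new intermediates and only edges between them
# and existing nodes (plus among themselves), never re-adding member-member
# edges already decided
.series_add_intermediates <- function(state, new_recs) {
  g <- state$map$graph
  params <- state$params
  for (nid in names(new_recs)) {
    rec <- new_recs[[nid]]
    state$records[[nid]] <- rec
    g <- igraph::add_vertices(g, 1L, name = nid, role = "intermediate",
                              smiles = rec$key)
    for (other in setdiff(igraph::V(g)$name, nid)) {
      s <- link_score(rec$mol, state$records[[other]]$mol,
                      beta = params$beta, timeout = params$mcs_timeout)$value
      if (s >= params$prune_threshold)
        g <- igraph::add_edges(g, c(nid, other), score = s)
    }
  }
  state$map$graph <- g
  state
}

#' Prune useless intermediates from a series map
#'
#' Removes intermediates that are disconnected from the main (member-
#' bearing) component or sit as leaf nodes on no cycle, iterating to a
#' fixpoint so pendant chains disappear entirely.
#'
#' @param state A `series_state`.
#' @return The updated `series_state`.
#' @export
prune_intermediates <- function(state) {
  g <- state$map$graph
  members <- .member_ids(state)
  repeat {
    roles <- igraph::V(g)$role
    comp <- igraph::components(g)
    main <- unique(comp$membership[members])
    drop <- which(roles == "intermediate" &
                    (!(comp$membership %in% main) | igraph::degree(g) <= 1L))
    if (!length(drop)) break
    g <- igraph::delete_vertices(g, drop)
  }
  state$map$graph <- g
  state$records <- state$records[igraph::V(g)$name]
  state$injected <- intersect(state$injected, igraph::V(g)$name)
  state
}

#' Build a perturbation map for a congeneric series with intermediates
#'
#' Repeats inject / rebuild / prune until no member-member link scores below
#' `threshold` (or the iteration cap is reached, in which case remaining bad
#' links are flagged in the map's warnings).
#'
#' @param members Named list of `compound_record`s or `molgraph`s.
#' @param threshold Series link-score threshold (default from `params`).
#' @param params A [run_config()].
#' @return A `perturbation_map` whose vertices carry `role` labels
#'   (`series_member` / `intermediate`); attribute `state` holds the final
#'   `series_state`.
#' @export
build_series_map <- function(members, threshold = NULL, params = run_config()) {
  if (!is.null(threshold)) params$series_threshold <- threshold
  base <- build_base_map(members, params)
  state <- new_series_state(base, attr(base, "records"), params)
  repeat {
    bad <- .bad_member_edges(state)
    if (!nrow(bad) || state$iteration >= params$max_iterations) break
    state$iteration <- state$iteration + 1L
    n_bad_before <- nrow(bad)
    state <- inject_intermediates(state)
    state <- prune_intermediates(state)
    if (nrow(.bad_member_edges(state)) >= n_bad_before &&
        !length(state$injected)) break   # no progress possible
  }
  map <- state$map
  ed <- .series_edge_df(map$graph, state$records)
  left <- ed[ed$member_edge & ed$score < params$series_threshold, , drop = FALSE]
  if (nrow(left))
    map$warnings <- c(map$warnings, sprintf(
      "member link(s) below threshold %.2f remain: %s",
      params$series_threshold,
      paste(paste(left$u, left$v, sep = "-"), collapse = ", ")))
  igraph::E(map$graph)$optimal <- FALSE
  map$members <- .member_ids(state)
  attr(map, "state") <- state
  map
}

#' Table of series-map statistics
#'
#' @param map A series `perturbation_map`.
#' @return One-row `data.frame`: `n_nodes`, `n_links`, `links_le_0.6`,
#'   `links_le_0.4` - the standard cost summary for a planned series map.
#' @export
series_summary <- function(map) {
  s <- igraph::E(map$graph)$score
  data.frame(n_nodes = igraph::vcount(map$graph), n_links = length(s),
             links_le_0.6 = sum(s <= 0.6), links_le_0.4 = sum(s <= 0.4))
}
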