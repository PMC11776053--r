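# Independent oracles used to verify the package's algorithms. These are
# deliberately naive (subset enumeration, plain DFS on edge lists) and share
# no code with the implementation under test.

# ---- molecules used across tests -------------------------------------------
SMI <- list(
  benzene  = "c1ccccc1",
  toluene  = "Cc1ccccc1",
  phenol   = "Oc1ccccc1",
  chlorobz = "Clc1ccccc1",
  biphenyl = "c1ccc(-c2ccccc2)cc1",
  naphthalene = "c1ccc2ccccc2c1",
  pyridine = "c1ccncc1",
  ethane   = "CC",
  propane  = "CCC",
  methane  = "C",
  acetate  = "CC(=O)[O-]",
  ethylamine = "CCN"
)

fix_mol <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (is.null(cache[[name]])) assign(name, parse_structure(SMI[[name]]), cache)
    cache[[name]]
  }
})

# ---- exhaustive MCS oracle --------------------------------------------------
# maximum connected common induced subgraph by brute force: every connected
# subset of a's atoms, every injective embedding into b that preserves
# adjacency, non-adjacency, and ring-bond character; element equality unless
# mismatches are allowed. Only for molecules of <= 8 heavy atoms.
oracle_mcs_size <- function(a, b, allow_mismatch = TRUE) {
  adjm <- function(m) {
    n <- length(m$elem)
    A <- matrix(0L, n, n)
    for (k in seq_len(nrow(m$bond))) {
      i <- m$bond[k, 1]; j <- m$bond[k, 2]
      A[i, j] <- A[j, i] <- if (m$ring_bond[k]) 2L else 1L  # 2 = ring bond
    }
    A
  }
  A <- adjm(a); B <- adjm(b)
  na <- length(a$elem); nb <- length(b$elem)
  connected_subset <- function(s) {
    if (length(s) <= 1) return(TRUE)
    seen <- s[1]; grow <- TRUE
    while (grow) {
      grow <- FALSE
      for (v in setdiff(s, seen)) if (any(A[v, seen] > 0)) {
        seen <- c(seen, v); grow <- TRUE
      }
    }
    length(seen) == length(s)
  }
  embeds <- function(sub, img) {
    for (x in seq_along(sub)) for (y in seq_along(sub)) {
      if (x == y) next
      if (A[sub[x], sub[y]] != B[img[x], img[y]]) return(FALSE)
    }
    if (!allow_mismatch && any(a$elem[sub] != b$elem[img])) return(FALSE)
    TRUE
  }
  try_embed <- function(sub, img) {
    k <- length(img) + 1
    if (k > length(sub)) return(embeds(sub, img))
    for (cand in setdiff(seq_len(nb), img)) {
      if (!allow_mismatch && a$elem[sub[k]] != b$elem[cand]) next
      if (try_embed(sub, c(img, cand))) return(TRUE)
    }
    FALSE
  }
  best <- 0L
  for (size in seq(min(na, nb), 1)) {
    if (size <= best) break
    subs <- utils::combn(na, size, simplify = FALSE)
    for (s in subs) {
      if (!connected_subset(s)) next
      if (try_embed(s, integer(0))) { best <- size; break }
    }
  }
  best
}

# ---- simple-path oracle ------------------------------------------------------
graph_edges_df <- function(g) {
  el <- igraph::as_edgelist(g)
  data.frame(u = el[, 1], v = el[, 2], score = igraph::E(g)$score,
             stringsAsFactors = FALSE)
}

oracle_simple_paths <- function(ed, a, b, max_len) {
  nb <- list()
  addnb <- function(u, v) nb[[u]] <<- c(nb[[u]], v)
  for (r in seq_len(nrow(ed))) { addnb(ed$u[r], ed$v[r]); addnb(ed$v[r], ed$u[r]) }
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == b) { out[[length(out) + 1]] <<- path; return() }
    if (length(path) > max_len) return()
    for (w in nb[[last]]) if (!(w %in% path)) walk(c(path, w))
  }
  if (!is.null(nb[[a]])) walk(a)
  out
}

oracle_edge_score <- function(ed, u, v) {
  hit <- (ed$u == u & ed$v == v) | (ed$u == v & ed$v == u)
  ed$score[hit][1]
}

# best path under the package's documented tie rules, computed from scratch
oracle_best_path <- function(g, a, b, min_score, max_dist) {
  ed <- graph_edges_df(g)
  ed <- ed[ed$score >= min_score, , drop = FALSE]
  paths <- oracle_simple_paths(ed, a, b, max_dist)
  if (!length(paths)) return(NULL)
  tab <- lapply(paths, function(p) {
    s <- vapply(seq_len(length(p) - 1),
                function(k) oracle_edge_score(ed, p[k], p[k + 1]), 0)
    list(ids = p, score = 1 / sum(1 / s^2), len = length(s), worst = min(s))
  })
  ord <- order(-vapply(tab, `[[`, 0, "score"),
               vapply(tab, `[[`, 0, "len"),
               -vapply(tab, `[[`, 0, "worst"),
               vapply(tab, function(x) paste(x$ids, collapse = "\x1f"), ""))
  tab[[ord[1]]]
}

# ---- map-construction oracle -------------------------------------------------
oracle_has_small_cycle <- function(ed, u, v, k) {
  hit <- which((ed$u == u & ed$v == v) | (ed$u == v & ed$v == u))
  alt <- oracle_simple_paths(ed[-hit[1], , drop = FALSE], u, v, k - 1)
  length(alt) > 0
}

oracle_corridor_nodes <- function(ed, a, b, msd) {
  paths <- oracle_simple_paths(ed, a, b, msd)
  if (!length(paths)) return(NULL)
  unique(unlist(paths))
}

# worst-first removal with the same tie rules and the finalization corridor
# pass; returns list(nodes, edges) with edges as sorted "u|v" keys
oracle_pair_map <- function(g, opt_ids, prune, max_cycle, msd) {
  ed <- graph_edges_df(g)
  a <- opt_ids[1]; b <- opt_ids[length(opt_ids)]
  okey <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "|")
  opt_keys <- okey(opt_ids[-length(opt_ids)], opt_ids[-1])
  ed$key <- okey(ed$u, ed$v)
  ed <- ed[ed$score >= prune | ed$key %in% opt_keys, , drop = FALSE]
  feas <- vapply(opt_keys, function(k) {
    r <- which(ed$key == k)
    oracle_has_small_cycle(ed, ed$u[r], ed$v[r], max_cycle)
  }, TRUE)
  ok <- function(e2) {
    for (ki in seq_along(opt_keys)) {
      r <- which(e2$key == opt_keys[ki])
      if (!length(r)) return(FALSE)
      if (feas[ki] && !oracle_has_small_cycle(e2, e2$u[r], e2$v[r], max_cycle))
        return(FALSE)
    }
    TRUE
  }
  ord <- order(ed$score, pmin(ed$u, ed$v), pmax(ed$u, ed$v))
  for (r in ed$key[ord]) {
    if (r %in% opt_keys) next
    e2 <- ed[ed$key != r, , drop = FALSE]
    if (ok(e2)) ed <- e2
  }
  keep <- oracle_corridor_nodes(ed, a, b, msd)
  if (!is.null(keep)) {
    e2 <- ed[ed$u %in% keep & ed$v %in% keep, , drop = FALSE]
    if (ok(e2)) ed <- e2
  }
  nodes <- sort(unique(c(ed$u, ed$v, a, b)))
  list(nodes = nodes, edges = sort(ed$key))
}

map_edge_keys <- function(map) {
  el <- igraph::as_edgelist(map$graph)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}
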