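# perturbation-map construction for ligand pairs

pair_params <- run_config(min_score = 0.3, prune_threshold = 0.2,
                          max_cycle = 4, max_subgraph_dist = 4)

test_that("a spare candidate closes the cycle around a direct optimal link", {
  g <- make_scored_graph(edges = data.frame(
    u = c("A", "A", "X"), v = c("B", "X", "B"), score = c(0.9, 0.8, 0.7)))
  p <- find_optimal_path(g, "A", "B", 0.5, 3)
  map <- build_pair_map(g, p, pair_params)
  expect_setequal(map_edge_keys(map), c("A|B", "A|X", "B|X"))
  expect_true(attr(map$constraint_report, "pass"))
  s <- map_statistics(map)
  expect_equal(s$worst_link_score, 0.7)
  expect_equal(s$ab_distance, 1)
  expect_equal(s$n_intermediates, 1)
  expect_equal(s$n_links, 3)
  expect_false(s$optimal_path_has_bridge)
})

test_that("with no cycle available the map keeps the bare path and flags every link", {
  g <- make_scored_graph(edges = data.frame(
    u = c("A", "X"), v = c("X", "B"), score = c(0.8, 0.8)))
  p <- find_optimal_path(g, "A", "B", 0.5, 3)
  map <- build_pair_map(g, p, pair_params)
  expect_setequal(map_edge_keys(map), c("A|X", "B|X"))
  expect_true(all(map$constraint_report$present))
  expect_true(all(!map$constraint_report$cycle_ok))
  expect_true(all(!map$constraint_report$feasible))
  expect_gt(length(map$warnings), 0)
  expect_true(map_statistics(map)$optimal_path_has_bridge)
})

test_that("construction equals the worst-first removal oracle on seeded graphs", {
  tested <- 0
  for (seed in 101:140) {
    g <- make_scored_graph(n_nodes = c(6L, 7L, 8L)[seed %% 3L + 1L],
                           seed = seed, p = 0.5)
    a <- "N01"; b <- rev(igraph::V(g)$name)[1]
    p <- tryCatch(find_optimal_path(g, a, b, pair_params$min_score,
                                    pair_params$max_dist),
                  alchemap_no_path = function(e) e$fallback_path)
    if (is.null(p)) next
    map <- build_pair_map(g, p, pair_params)
    want <- oracle_pair_map(g, p$node_ids, pair_params$prune_threshold,
                            pair_params$max_cycle, pair_params$max_subgraph_dist)
    expect_identical(map_edge_keys(map), want$edges, info = sprintf("seed %d", seed))
    expect_identical(sort(igraph::V(map$graph)$name), want$nodes,
                     info = sprintf("seed %d", seed))
    # constraint 1: optimal links always retained
    opt <- paste(pmin(p$node_ids[-length(p$node_ids)], p$node_ids[-1]),
                 pmax(p$node_ids[-length(p$node_ids)], p$node_ids[-1]), sep = "|")
    expect_true(all(opt %in% map_edge_keys(map)))
    # constraint 2 wherever the oracle finds it feasible on the pruned graph
    rep <- map$constraint_report
    expect_true(all(rep$cycle_ok[rep$feasible]))
    tested <- tested + 1
  }
  expect_gte(tested, 30)
})

test_that("the output is locally minimal: no further non-optimal edge is removable", {
  for (seed in c(103, 111, 119)) {
    g <- make_scored_graph(n_nodes = 7, seed = seed, p = 0.5)
    p <- tryCatch(find_optimal_path(g, "N01", "N07", 0.3, 3),
                  alchemap_no_path = function(e) e$fallback_path)
    if (is.null(p)) next
    map <- build_pair_map(g, p, pair_params)
    ed <- graph_edges_df(map$graph)
    ed$key <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v), sep = "|")
    opt <- paste(pmin(p$node_ids[-length(p$node_ids)], p$node_ids[-1]),
                 pmax(p$node_ids[-length(p$node_ids)], p$node_ids[-1]), sep = "|")
    feas <- map$constraint_report$feasible
    for (r in which(!(ed$key %in% opt))) {
      e2 <- ed[-r, , drop = FALSE]
      still_ok <- all(vapply(seq_along(opt), function(k) {
        u <- p$node_ids[k]; v <- p$node_ids[k + 1]
        if (!feas[k]) return(TRUE)
        oracle_has_small_cycle(e2, u, v, pair_params$max_cycle)
      }, TRUE))
      expect_false(still_ok, info = sprintf("seed %d edge %s", seed, ed$key[r]))
    }
  }
})

test_that("corridor extraction keeps exactly the nodes on short A-B paths and is idempotent", {
  star <- make_scored_graph(edges = data.frame(
    u = c("A", "H", "H"), v = c("H", "B", "P"), score = c(0.9, 0.9, 0.9)))
  s <- extract_ab_subgraph(star, 2, endpoints = c("A", "B"))
  expect_setequal(igraph::V(s)$name, c("A", "H", "B"))
  s2 <- extract_ab_subgraph(s, 2, endpoints = c("A", "B"))
  expect_identical(sort(igraph::V(s2)$name), sort(igraph::V(s)$name))
  expect_equal(igraph::ecount(s2), igraph::ecount(s))
  disc <- make_scored_graph(edges = data.frame(u = "A", v = "H", score = 0.9),
                            n_nodes = 0)
  disc <- igraph::add_vertices(disc, 1, name = "B")
  expect_error(extract_ab_subgraph(disc, 3, endpoints = c("A", "B")),
               "disconnected")
})

test_that("constraint checks distinguish cycle sizes", {
  cyc5 <- make_scored_graph(edges = data.frame(
    u = c("A", "B", "C", "D", "E"), v = c("B", "C", "D", "E", "A"),
    score = rep(0.8, 5)))
  links <- cbind("A", "B")
  r4 <- check_constraints(cyc5, links, max_cycle = 4)
  expect_false(r4$cycle_ok)
  r5 <- check_constraints(cyc5, links, max_cycle = 5)
  expect_true(r5$cycle_ok)
})

test_that("bridges are exactly the cut edges", {
  tree <- make_scored_graph(edges = data.frame(
    u = c("A", "B", "B"), v = c("B", "C", "D"), score = rep(0.9, 3)))
  expect_equal(nrow(find_bridges(tree)), 3)
  cyc <- make_scored_graph(edges = data.frame(
    u = c("A", "B", "C"), v = c("B", "C", "A"), score = rep(0.9, 3)))
  expect_equal(nrow(find_bridges(cyc)), 0)
  barbell <- make_scored_graph(edges = data.frame(
    u = c("A", "B", "C", "D", "E", "F", "C"),
    v = c("B", "C", "A", "E", "F", "D", "D"),
    score = rep(0.9, 7)))
  br <- find_bridges(barbell)
  expect_equal(nrow(br), 1)
  expect_setequal(c(br$u, br$v), c("C", "D"))
})

test_that("maps round-trip through GraphML and CSV", {
  g <- make_scored_graph(edges = data.frame(
    u = c("A", "A", "X"), v = c("B", "X", "B"), score = c(0.9, 0.8, 0.7)))
  p <- find_optimal_path(g, "A", "B", 0.5, 3)
  map <- build_pair_map(g, p, pair_params)
  gml <- withr::local_tempfile(fileext = ".graphml")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_map_graphml(map, gml)
  back <- read_map_graphml(gml)
  expect_identical(map_edge_keys(back), map_edge_keys(map))
  expect_identical(back$endpoints, map$endpoints)
  expect_identical(back$optimal_path, map$optimal_path)
  expect_equal(sort(igraph::E(back$graph)$score), sort(igraph::E(map$graph)$score))
  write_map_csv(map, csv)
  back2 <- read_map_csv(csv)
  expect_identical(map_edge_keys(back2), map_edge_keys(map))
})
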