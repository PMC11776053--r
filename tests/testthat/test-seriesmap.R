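# congeneric-series maps

series_params <- run_config()

test_that("tiny series produce the expected base maps", {
  two <- make_congeneric_series(fixture_spec(substituents = c("", "C"),
                                             distant = FALSE))
  m2 <- build_base_map(two, series_params)
  expect_equal(igraph::ecount(m2$graph), 1)
  three <- make_congeneric_series(fixture_spec(substituents = c("", "C", "O"),
                                               distant = FALSE))
  m3 <- build_base_map(three, series_params)
  # three mutually similar compounds: the triangle survives the cycle constraint
  expect_equal(igraph::ecount(m3$graph), 3)
  expect_error(build_base_map(two[1], series_params), "at least two")
})

test_that("the base map obeys connectivity, distance, and cycle-cover constraints", {
  series <- make_congeneric_series(fixture_spec())
  base <- build_base_map(series, series_params)
  g <- base$graph
  expect_true(igraph::is_connected(g))
  d <- igraph::distances(g)
  expect_true(all(d <= series_params$base_dmax))
  # against the removal lattice: no single further edge is removable without
  # breaking a constraint (worst-first local minimality)
  full <- candidate_graph(score_matrix(series), min_score = 0)
  for (k in seq_len(igraph::ecount(g))) {
    g2 <- igraph::delete_edges(g, k)
    el <- igraph::as_edgelist(g2)
    violates <- !igraph::is_connected(g2) ||
      any(!is.finite(igraph::distances(g2))) ||
      any(igraph::distances(g2) > series_params$base_dmax) ||
      !all(vapply(seq_len(nrow(el)), function(r) {
        u <- el[r, 1]; v <- el[r, 2]
        !alchemap:::.on_small_cycle(full, u, v, series_params$max_cycle) ||
          alchemap:::.on_small_cycle(g2, u, v, series_params$max_cycle)
      }, TRUE))
    expect_true(violates, info = sprintf("edge %d should be needed", k))
  }
})

test_that("a series with no bad edges is a fixpoint of injection", {
  near <- make_congeneric_series(fixture_spec(distant = FALSE))
  base <- build_series_map(near, params = series_params)
  st <- attr(base, "state")
  expect_equal(st$iteration, 0L)
  expect_length(st$injected, 0)
  base2 <- build_base_map(near, series_params)
  expect_identical(map_edge_keys(base), map_edge_keys(base2))
})

test_that("pendant intermediates are pruned to a fixpoint", {
  series <- make_congeneric_series(fixture_spec(substituents = c("", "C"),
                                                distant = FALSE))
  base <- build_base_map(series, series_params)
  st <- alchemap:::new_series_state(base, attr(base, "records"), series_params)
  # hang a two-node chain of intermediates off one member
  chain <- list(
    X900 = compound_record(fix_mol("phenol"), "X900", "intermediate"),
    X901 = compound_record(fix_mol("naphthalene"), "X901", "intermediate"))
  st$records <- c(st$records, chain)
  g <- st$map$graph
  g <- igraph::add_vertices(g, 2, name = c("X900", "X901"), role = "intermediate",
                            smiles = c(chain$X900$key, chain$X901$key))
  g <- igraph::add_edges(g, c("M01", "X900", "X900", "X901"), score = c(0.9, 0.5))
  st$map$graph <- g
  st <- prune_intermediates(st)
  expect_setequal(igraph::V(st$map$graph)$name, c("M01", "M02"))
})

test_that("the full series build removes all sub-threshold member links", {
  series <- make_congeneric_series(fixture_spec())
  map <- build_series_map(series, params = series_params)
  st <- attr(map, "state")
  g <- map$graph
  roles <- igraph::V(g)$role
  names(roles) <- igraph::V(g)$name
  ed <- graph_edges_df(g)
  member_edge <- roles[ed$u] == "series_member" & roles[ed$v] == "series_member"
  expect_true(all(ed$score[member_edge] >= series_params$series_threshold))
  expect_length(map$warnings, 0)
  # all members present, connected, within one component
  expect_true(all(map$members %in% igraph::V(g)$name))
  expect_true(igraph::is_connected(g))
  # intermediates are neither leaves nor disconnected
  inter <- names(roles)[roles == "intermediate"]
  expect_gte(length(inter), 1)
  expect_true(all(igraph::degree(g, inter) >= 2))
  # injected compounds are deduplicated against members and each other
  keys <- vapply(st$records, function(r) r$key, "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("series builds are byte-identical across runs", {
  series <- make_congeneric_series(fixture_spec())
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_map_graphml(build_series_map(series, params = series_params), f1)
  write_map_graphml(build_series_map(series, params = series_params), f2)
  expect_identical(readLines(f1), readLines(f2))
})
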