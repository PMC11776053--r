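# Deterministic fixtures ------------------------------------------------------
#
# Toy congeneric series and abstract scored graphs used by examples and the
# test suite. They stand in for real lead-optimization series (which require
# external datasets and a preparation pipeline) while exercising the same
# machinery: a shared aromatic scaffold, small substituent variations, and
# optionally one deliberately distant member carrying two extra fused rings
# so that at least one pairwise link score drops below 0.4 - the regime
# where intermediate injection becomes necessary.

#' Specification of a toy congeneric series
#'
#' @param scaffold Scaffold SMILES; must start with a ring-atom so that
#'   substituent prefixes attach to it (default benzene).
#' @param substituents Character vector of substituent SMILES prefixes
#'   (`""` = unsubstituted scaffold).
#' @param distant Include the distant member (scaffold homologue with two
#'   extra fused rings and a hydroxymethyl substituent, 16 heavy atoms for
#'   the benzene scaffold)?
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(scaffold = "c1ccccc1",
                         substituents = c("", "C", "O", "Cl"),
                         distant = TRUE) {
  structure(list(scaffold = scaffold, substituents = substituents,
                 distant = distant),
            class = "fixture_spec")
}

#' Generate a toy congeneric series
#'
#' Deterministic: the same spec always yields the same molecules in the
#' same order, with net charge 0 throughout. With `distant = TRUE` the last
#' member is a tricyclic homologue whose link score to the smallest member
#' falls below 0.4.
#'
#' @param spec A [fixture_spec()].
#' @return Named list of `compound_record`s with role `series_member`.
#' @examples
#' series <- make_congeneric_series(fixture_spec())
#' names(series)
#' @export
make_congeneric_series <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  smiles <- paste0(spec$substituents, spec$scaffold)
  if (spec$distant) {
    distant <- if (identical(spec$scaffold, "c1ccccc1"))
      "OCc1ccc2cc3ccccc3cc2c1" else
      paste0("OC", spec$scaffold, "c1ccc2ccccc2c1")
    smiles <- c(smiles, distant)
  }
  out <- list()
  for (k in seq_along(smiles)) {
    id <- sprintf("M%02d", k)
    rec <- compound_record(parse_structure(smiles[k]), id, "series_member")
    if (net_charge(rec$mol) != 0L)
      stop("fixture series members must be neutral: ", smiles[k])
    out[[id]] <- rec
  }
  out
}

#' Construct an abstract scored graph
#'
#' Bypasses all chemistry: builds an igraph whose edges carry link-score
#' values directly, for exercising the path-search and map-construction
#' algorithms against brute-force oracles.
#'
#' @param n_nodes Number of nodes (named `N01`, `N02`, ...); ignored when
#'   `edges` names other nodes.
#' @param edges Optional `data.frame` with columns `u`, `v`, `score`; when
#'   omitted a random connected graph is drawn.
#' @param seed Seed for the random variant (required then, for
#'   reproducibility).
#' @param p Edge probability of the random variant.
#' @return An igraph with a `score` edge attribute.
#' @export
make_scored_graph <- function(n_nodes = NULL, edges = NULL, seed = NULL, p = 0.4) {
  if (!is.null(edges)) {
    stopifnot(all(c("u", "v", "score") %in% names(edges)))
    if (any(edges$score <= 0 | edges$score > 1))
      stop("scores must lie in (0, 1]")
    ids <- sort(unique(c(edges$u, edges$v)))
    if (!is.null(n_nodes) && n_nodes > length(ids))
      ids <- union(ids, sprintf("N%02d", seq_len(n_nodes)))
    g <- igraph::make_empty_graph(length(ids), directed = FALSE)
    igraph::V(g)$name <- ids
    g <- igraph::add_edges(g, t(cbind(edges$u, edges$v)))
    igraph::E(g)$score <- edges$score
    return(g)
  }
  stopifnot(!is.null(n_nodes), n_nodes >= 2, !is.null(seed))
  withr_seed <- function(code) { # localize RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    ids <- sprintf("N%02d", seq_len(n_nodes))
    el <- t(utils::combn(ids, 2L))
    keep <- stats::runif(nrow(el)) < p
    # guarantee connectivity with a spanning path over consecutive ids
    onpath <- (match(el[, 2L], ids) - match(el[, 1L], ids)) == 1L
    keep <- keep | onpath
    el <- el[keep, , drop = FALSE]
    g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
    igraph::V(g)$name <- ids
    g <- igraph::add_edges(g, t(el))
    igraph::E(g)$score <- round(stats::runif(nrow(el), 0.05, 1), 3)
    g
  })
}
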