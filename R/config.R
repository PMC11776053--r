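# Run configuration -----------------------------------------------------------

#' Planner configuration
#'
#' Bundles the thresholds steering path selection and map construction. The
#' defaults are the settings used throughout the package's reference
#' workflow: `beta = 0.1` (the Lomap default link-score scaling),
#' `min_score = 0.5` for optimal-path links, `prune_threshold = 0.2` for the
#' map's candidate edges, `max_dist = 3` edges for the optimal path,
#' `max_cycle = 4` for the thermodynamic-cycle size protecting each optimal
#' link, and `max_subgraph_dist = 4` for the A-B corridor. Series mode
#' treats member-member links scoring below `series_threshold = 0.6` as
#' needing intermediates.
#'
#' @param beta Link-score scaling parameter (> 0).
#' @param min_score Minimum admissible link score on optimal-path edges,
#'   in (0, 1).
#' @param prune_threshold Link-score pruning threshold for map edges.
#' @param max_dist Maximum optimal-path length in edges (>= 1).
#' @param max_cycle Maximum admissible cycle size (>= 3).
#' @param max_subgraph_dist Maximum A-B path length defining the corridor.
#' @param series_threshold Link-score threshold for series injection.
#' @param base_dmax Maximum member-member graph distance kept in the series
#'   base map.
#' @param max_iterations Cap on series injection rounds.
#' @param mcs_timeout Seconds per MCS computation.
#' @param subgraph_mode When corridor extraction is applied during map
#'   construction: `"final"` (once, at finalization; the default) or
#'   `"during"` (after every kept removal as well).
#' @return A `run_config` list.
#' @export
run_config <- function(beta = 0.1, min_score = 0.5, prune_threshold = 0.2,
                       max_dist = 3, max_cycle = 4, max_subgraph_dist = 4,
                       series_threshold = 0.6, base_dmax = 6,
                       max_iterations = 5, mcs_timeout = 10,
                       subgraph_mode = c("final", "during")) {
  subgraph_mode <- match.arg(subgraph_mode)
  stopifnot(beta > 0, min_score > 0, min_score < 1,
            prune_threshold >= 0, prune_threshold < 1,
            max_dist >= 1, max_cycle >= 3, max_subgraph_dist >= 1,
            series_threshold > 0, series_threshold < 1,
            base_dmax >= 1, max_iterations >= 1, mcs_timeout > 0)
  structure(list(beta = beta, min_score = min_score,
                 prune_threshold = prune_threshold, max_dist = max_dist,
                 max_cycle = max_cycle, max_subgraph_dist = max_subgraph_dist,
                 series_threshold = series_threshold, base_dmax = base_dmax,
                 max_iterations = max_iterations, mcs_timeout = mcs_timeout,
                 subgraph_mode = subgraph_mode),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Load a configuration from a YAML file
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file with `run_config` fields.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}
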