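# Link and path scores -------------------------------------------------------

#' Link score between two compounds
#'
#' Similarity-derived difficulty proxy for a planned alchemical
#' transformation: `S_e = exp(-beta * (N_A + N_B - 2 * N_MCS))`, where the
#' counts are heavy atoms of the two compounds and of their maximum common
#' substructure (computed with atom-type mismatches allowed, so in-place
#' element mutations are not penalized). `N_A + N_B - 2 N_MCS` is the number
#' of atoms that must be inserted or deleted; the score lies in (0, 1] and
#' equals 1 exactly when the two compounds are identical.
#'
#' @param a,b `molgraph` objects (or SMILES strings, parsed on the fly).
#' @param beta Positive scaling parameter; default 0.1 (the Lomap default).
#' @param timeout Per-pair MCS time budget in seconds.
#' @return Object of class `link_score`: list with `value`, `beta`, `n_a`,
#'   `n_b`, `n_mcs`, `timed_out`.
#' @examples
#' link_score("Cc1ccccc1", "c1ccccc1")$value  # exp(-0.1) = 0.9048
#' @export
link_score <- function(a, b, beta = 0.1, timeout = 10) {
  a <- .as_molgraph(a); b <- .as_molgraph(b)
  stopifnot(beta > 0)
  mcs <- mcs_size_cached(a, b, allow_element_mismatch = TRUE, timeout = timeout)
  delta <- n_heavy(a) + n_heavy(b) - 2L * mcs$n_mcs
  structure(list(value = exp(-beta * delta), beta = beta,
                 n_a = n_heavy(a), n_b = n_heavy(b), n_mcs = mcs$n_mcs,
                 timed_out = mcs$timed_out),
            class = "link_score")
}

#' @export
print.link_score <- function(x, ...) {
  cat(sprintf("<link_score> %.4f  (N_A=%d, N_B=%d, N_MCS=%d, beta=%g)%s\n",
              x$value, x$n_a, x$n_b, x$n_mcs, x$beta,
              if (x$timed_out) " [MCS timed out]" else ""))
  invisible(x)
}

.as_molgraph <- function(x) {
  if (is_molgraph(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_structure(x))
  if (is.list(x) && is_molgraph(x$mol)) return(x$mol)  # compound record
  stop("expected a molgraph, compound record, or SMILES string")
}

#' Path score of a transformation path
#'
#' Quality measure of a multi-step transformation: the harmonic mean of the
#' squared link scores of its edges divided by the path length, which
#' reduces to `1 / sum(1 / S_e^2)`. Higher is better; adding any edge to a
#' path strictly decreases the score, so the measure penalizes both weak
#' links and unnecessary length.
#'
#' @param edge_scores Numeric vector of link-score values in (0, 1] (or a
#'   list of `link_score` objects).
#' @return Object of class `path_score`: list with `value`, `edge_scores`,
#'   `length`.
#' @examples
#' path_score(c(1, 1))$value     # 0.5
#' @export
path_score <- function(edge_scores) {
  if (is.list(edge_scores))
    edge_scores <- vapply(edge_scores, function(s) s$value, 0)
  if (!length(edge_scores)) stop("a path must contain at least one edge")
  if (any(edge_scores <= 0 | edge_scores > 1))
    stop("edge scores must lie in (0, 1]")
  structure(list(value = 1 / sum(edge_scores^-2),
                 edge_scores = edge_scores,
                 length = length(edge_scores)),
            class = "path_score")
}

#' @export
print.path_score <- function(x, ...) {
  cat(sprintf("<path_score> %.4f over %d edge(s)\n", x$value, x$length))
  invisible(x)
}

#' All-pairs link-score matrix
#'
#' Symmetric matrix of link-score values over a set of compounds, with unit
#' diagonal. MCS results are cached by canonical structure key, so repeated
#' calls over overlapping compound sets (as in series mode) do not recompute
#' pairs. Cost grows quadratically with the number of compounds.
#'
#' @param compounds Named list of `molgraph` objects or compound records.
#' @param beta Link-score scaling parameter.
#' @param timeout Per-pair MCS time budget (seconds).
#' @return Numeric matrix with compound ids as dimnames; attribute
#'   `timed_out_pairs` lists pairs whose MCS search hit the budget.
#' @export
score_matrix <- function(compounds, beta = 0.1, timeout = 10) {
  stopifnot(length(compounds) >= 2L)
  mols <- lapply(compounds, .as_molgraph)
  ids <- names(mols)
  if (is.null(ids) || anyDuplicated(ids)) ids <- as.character(seq_along(mols))
  n <- length(mols)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  slow <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- link_score(mols[[i]], mols[[j]], beta = beta, timeout = timeout)
      m[i, j] <- m[j, i] <- s$value
      if (s$timed_out) slow <- c(slow, paste(ids[i], ids[j], sep = "~"))
    }
  }
  attr(m, "timed_out_pairs") <- slow
  m
}
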