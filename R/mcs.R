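# Maximum common substructure ------------------------------------------------
#
# Connected MCS between two molecular graphs by McGregor-style backtracking:
# grow a one-to-one atom mapping outward from a seed pair, branching over
# "map this frontier atom to each feasible partner" and "exclude it". The
# mapping is an induced common subgraph (bonds present/absent must agree on
# both sides), bond orders are ignored (alchemical transformations routinely
# change them), and ring bonds may only map to ring bonds so that the common
# core never tears a ring open. With `allow_element_mismatch` the atom
# compatibility is purely topological; mismatched element pairs are recorded.
#
# Because every parsed molecule is rebuilt from its canonical SMILES, atom
# indices are themselves canonical, and the deterministic tie-break
# (max size, then fewest mismatches, then lexicographically smallest pair
# list) makes the search reproducible.

#' Maximum common substructure of two molecules
#'
#' @param a,b `molgraph` objects.
#' @param allow_element_mismatch If `TRUE` (default) atoms of different
#'   elements may be paired; such pairs are reported in `mismatched_pairs`.
#'   This tolerance is what lets a planned transformation mutate an atom in
#'   place instead of deleting and regrowing it.
#' @param timeout Seconds before the search stops and returns the best
#'   mapping found so far (flagged `timed_out`).
#' @param max_nodes Search-node cap serving the same purpose as `timeout`.
#' @return An object of class `mcs_mapping`: list with `pairs` (two-column
#'   matrix of atom indices in `a` and `b`), `n_mcs`, `mismatched_pairs`,
#'   and `timed_out`.
#' @examples
#' tol <- parse_structure("Cc1ccccc1")
#' phe <- parse_structure("Oc1ccccc1")
#' compute_mcs(tol, phe)$n_mcs  # 7: the ring plus the mismatched C/O pair
#' @export
compute_mcs <- function(a, b, allow_element_mismatch = TRUE, timeout = 10,
                        max_nodes = 2e5) {
  stopifnot(is_molgraph(a), is_molgraph(b))
  na <- n_heavy(a); nb <- n_heavy(b)
  admA <- .adj_matrix(a); admB <- .adj_matrix(b)
  ringA <- .ring_matrix(a); ringB <- .ring_matrix(b)

  compat <- outer(seq_len(na), seq_len(nb), function(i, j) {
    if (allow_element_mismatch) rep(TRUE, length(i)) else a$elem[i] == b$elem[j]
  })

  env <- new.env(parent = emptyenv())
  env$best_size <- 0L
  env$best_mism <- .Machine$integer.max
  env$best_flat <- integer(0)
  env$best_map <- integer(0)
  env$nodes <- 0L
  env$timed_out <- FALSE
  deadline <- proc.time()[["elapsed"]] + timeout

  mapA <- integer(na)          # 0 = unmapped; else index in b
  usedB <- logical(nb)
  excluded <- logical(na)

  mism_count <- function(map) sum(a$elem[which(map > 0L)] != b$elem[map[map > 0L]])

  update_best <- function(map, size) {
    if (size < env$best_size) return(invisible())
    idx <- which(map > 0L)
    flat <- as.vector(rbind(idx, map[idx]))
    mism <- sum(a$elem[idx] != b$elem[map[idx]])
    better <-
      size > env$best_size ||
      (mism < env$best_mism) ||
      (mism == env$best_mism && .lex_less(flat, env$best_flat))
    if (better) {
      env$best_size <- size
      env$best_mism <- mism
      env$best_flat <- flat
      env$best_map <- map
    }
    invisible()
  }

  feasible <- function(i, j, map) {
    if (usedB[j] || !compat[i, j]) return(FALSE)
    idx <- which(map > 0L)
    for (aatom in idx) {
      ea <- admA[i, aatom]; eb <- admB[j, map[aatom]]
      if (ea != eb) return(FALSE)                 # induced-subgraph condition
      if (ea && (ringA[i, aatom] != ringB[j, map[aatom]])) return(FALSE)
    }
    TRUE
  }

  recurse <- function(size) {
    env$nodes <- env$nodes + 1L
    if (env$nodes %% 512L == 0L && proc.time()[["elapsed"]] > deadline) {
      env$timed_out <- TRUE
      return()
    }
    if (env$nodes > max_nodes) { env$timed_out <- TRUE; return() }
    update_best(mapA, size)
    avail <- which(mapA == 0L & !excluded)
    if (size + min(length(avail), sum(!usedB)) < env$best_size) return()
    # frontier: unmapped, unexcluded atoms adjacent to the mapped core
    mapped <- which(mapA > 0L)
    if (!length(mapped)) return()
    front <- avail[vapply(avail, function(i) any(admA[i, mapped]), TRUE)]
    if (!length(front)) return()
    i <- front[1L]
    for (j in which(!usedB)) {
      if (env$timed_out) return()
      if (feasible(i, j, mapA)) {
        mapA[i] <<- j; usedB[j] <<- TRUE
        recurse(size + 1L)
        mapA[i] <<- 0L; usedB[j] <<- FALSE
      }
    }
    if (env$timed_out) return()
    excluded[i] <<- TRUE
    recurse(size)
    excluded[i] <<- FALSE
  }

  for (i in seq_len(na)) {
    if (env$timed_out) break
    # any connected common subgraph has a smallest a-atom: seed there and
    # forbid smaller atoms in this subtree to avoid duplicate exploration
    if (i > 1L) excluded[seq_len(i - 1L)] <- TRUE
    for (j in seq_len(nb)) {
      if (env$timed_out) break
      if (compat[i, j]) {
        mapA[i] <- j; usedB[j] <- TRUE
        recurse(1L)
        mapA[i] <- 0L; usedB[j] <- FALSE
      }
    }
    excluded[] <- FALSE
  }

  idx <- which(env$best_map > 0L)
  pairs <- cbind(a = idx, b = env$best_map[idx])
  mism <- pairs[a$elem[pairs[, 1L]] != b$elem[pairs[, 2L]], , drop = FALSE]
  structure(list(pairs = pairs, n_mcs = nrow(pairs), mismatched_pairs = mism,
                 timed_out = env$timed_out),
            class = "mcs_mapping")
}

#' @export
print.mcs_mapping <- function(x, ...) {
  cat(sprintf("<mcs_mapping> %d mapped atoms, %d element mismatches%s\n",
              x$n_mcs, nrow(x$mismatched_pairs),
              if (x$timed_out) " (search timed out; best found)" else ""))
  invisible(x)
}

.adj_matrix <- function(mol) {
  n <- n_heavy(mol)
  m <- matrix(FALSE, n, n)
  if (nrow(mol$bond))
    m[mol$bond[, 1:2, drop = FALSE]] <- m[mol$bond[, 2:1, drop = FALSE]] <- TRUE
  m
}

.ring_matrix <- function(mol) {
  n <- n_heavy(mol)
  m <- matrix(FALSE, n, n)
  rb <- mol$bond[mol$ring_bond, , drop = FALSE]
  if (nrow(rb)) m[rb[, 1:2, drop = FALSE]] <- m[rb[, 2:1, drop = FALSE]] <- TRUE
  m
}

# TRUE if integer vector x is lexicographically smaller than y (same length
# context: used only to break ties between equal-size mappings)
.lex_less <- function(x, y) {
  if (!length(y)) return(TRUE)
  n <- min(length(x), length(y))
  for (k in seq_len(n)) {
    if (x[k] < y[k]) return(TRUE)
    if (x[k] > y[k]) return(FALSE)
  }
  length(x) < length(y)
}

# cached MCS size between two molecules, keyed by canonical structure keys;
# link scores only need the size, so mappings themselves are not cached
# (atom order differs between graphs sharing a key).
.mcs_cache <- new.env(parent = emptyenv())

mcs_size_cached <- function(a, b, allow_element_mismatch = TRUE, timeout = 10) {
  ka <- canonical_key(a); kb <- canonical_key(b)
  if (ka > kb) { tmp <- ka; ka <- kb; kb <- tmp }
  key <- paste(ka, kb, allow_element_mismatch, sep = "\x1f")
  hit <- .mcs_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- compute_mcs(a, b, allow_element_mismatch, timeout)
  out <- list(n_mcs = res$n_mcs, timed_out = res$timed_out)
  assign(key, out, envir = .mcs_cache)
  out
}

clear_mcs_cache <- function() {
  rm(list = ls(.mcs_cache), envir = .mcs_cache)
  invisible()
}
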