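# Exhaustive intermediate generation -----------------------------------------
#
# Intermediates are enumerated by editing the start compound toward the
# maximum common substructure it shares with the target, one chemical step at
# a time:
#
#   a  mutate a core (MCS) atom whose element/charge differs from its mapped
#      target atom
#   b  delete one acyclic non-core atom (ring atoms are never deleted singly:
#      that would leave open valences)
#   c  delete a complete non-core ring system attached by a single bond,
#      capping with (implicit) hydrogen
#   d  the same deletion capped with a methyl carbon
#   e  delete the non-core portion of a fused ring system, re-kekulizing the
#      ring that remains
#
# A LIFO compound pool closes the edit relation: every popped compound is
# expanded by all applicable single edits, new structures (by canonical key)
# are pushed back, and the pool drains in finitely many pops because each
# edit strictly reduces the number of atoms outside the core frame or the
# number of element/charge mismatches inside it. The core frame is tracked
# across edits by projecting the start<->target MCS mapping through each
# edit's atom-survival map.

# --- atomic edit helpers -----------------------------------------------------

# delete atoms; returns new graph plus the surviving old indices in new order
delete_atoms <- function(mol, idx) {
  keep <- setdiff(seq_len(n_heavy(mol)), idx)
  newix <- integer(n_heavy(mol))
  newix[keep] <- seq_along(keep)
  b <- mol$bond
  b <- b[b[, 1L] %in% keep & b[, 2L] %in% keep, , drop = FALSE]
  b[, 1L] <- newix[b[, 1L]]
  b[, 2L] <- newix[b[, 2L]]
  list(mol = new_molgraph(mol$elem[keep], mol$charge[keep], mol$aromatic[keep], b),
       survivors = keep)
}

set_atom <- function(mol, i, elem, charge) {
  new_molgraph(replace(mol$elem, i, elem), replace(mol$charge, i, charge),
               mol$aromatic, mol$bond)
}

add_atom <- function(mol, elem, charge, bond_to, order = 1L) {
  n <- n_heavy(mol) + 1L
  new_molgraph(c(mol$elem, elem), c(mol$charge, charge), c(mol$aromatic, FALSE),
               rbind(mol$bond, c(bond_to, n, order)))
}

# all chordless simple cycles (length 3..max_len): for fused polycyclics this
# recovers the individual rings a chemist would draw
chordless_rings <- function(mol, max_len = 8L) {
  n <- n_heavy(mol)
  adm <- .adj_matrix(mol)
  adj <- lapply(seq_len(n), function(i) which(adm[i, ]))
  found <- new.env(parent = emptyenv())
  rings <- list()
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == path[1L] && length(path) >= 3L) {
        key <- paste(sort(path), collapse = ",")
        if (is.null(found[[key]])) {
          assign(key, TRUE, envir = found)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (w > path[1L] && !(w %in% path) && length(path) < max_len) {
        dfs(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) if (length(adj[[s]]) >= 2L) dfs(s)
  # chordless: a cycle of k atoms spans exactly k bonds
  rings[vapply(rings, function(r) sum(adm[r, r]) / 2 == length(r), TRUE)]
}

# connected components of the subgraph made of ring bonds: one per ring system
ring_systems <- function(mol) {
  rb <- mol$bond[mol$ring_bond, , drop = FALSE]
  if (!nrow(rb)) return(list())
  g <- igraph::make_empty_graph(n_heavy(mol), directed = FALSE)
  g <- igraph::add_edges(g, t(rb[, 1:2, drop = FALSE]))
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 3L)
  lapply(keep, function(k) which(comp$membership == k))
}

# restore an alternating double-bond pattern over the formerly aromatic atoms
# `atoms` (new indices) after part of their ring system was deleted; returns
# the fixed graph or NULL when no kekule assignment exists
rekekulize <- function(mol, atoms) {
  arom <- atoms[mol$aromatic[atoms]]
  if (!length(arom)) return(mol)
  b <- mol$bond
  # atoms already holding a double/triple bond are satisfied
  dsum <- integer(n_heavy(mol))
  for (k in seq_len(nrow(b))) if (b[k, 3L] >= 2L) {
    dsum[b[k, 1L]] <- dsum[b[k, 1L]] + 1L
    dsum[b[k, 2L]] <- dsum[b[k, 2L]] + 1L
  }
  need <- arom[dsum[arom] == 0L]
  optional <- mol$elem %in% c("N", "O", "S")   # pyrrole-type atoms may stay single
  cand <- which(b[, 3L] == 1L & b[, 1L] %in% need & b[, 2L] %in% need)
  match_edges <- function(unsat, used_edges) {
    unsat_req <- unsat[!optional[unsat]]
    if (!length(unsat_req)) return(used_edges)
    i <- unsat_req[1L]
    for (k in cand) {
      if (k %in% used_edges) next
      u <- b[k, 1L]; v <- b[k, 2L]
      if (u != i && v != i) next
      other <- if (u == i) v else u
      if (!(other %in% unsat)) next
      res <- match_edges(setdiff(unsat, c(i, other)), c(used_edges, k))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  sel <- match_edges(need, integer(0))
  if (is.null(sel)) return(NULL)
  b[sel, 3L] <- 2L
  new_molgraph(mol$elem, mol$charge, mol$aromatic, b)
}

# --- single-step edit enumeration -------------------------------------------

#' Enumerate all single-edit intermediates of one compound
#'
#' Applies every applicable generation procedure (a-e, see the package
#' vignette) exactly once and returns the chemically valid results. `map` is
#' the projection of the start/target MCS onto `mol`'s atoms: `map[i]` is the
#' matched atom index in `target`, or `NA` for atoms outside the common core.
#'
#' @param mol A `molgraph` to edit.
#' @param target The target `molgraph` whose core frame is being approached.
#' @param map Integer vector, length `n_heavy(mol)`; `NA` marks non-core atoms.
#' @return List of edits, each a list with `mol` (valid, keyed `molgraph`),
#'   `map` (projected core frame), and `proc` (procedure label `"a"`..`"e"`).
#' @export
enumerate_edits <- function(mol, target, map) {
  stopifnot(is_molgraph(mol), is_molgraph(target), length(map) == n_heavy(mol))
  out <- list()
  emit <- function(newmol, newmap, proc) {
    if (is.null(newmol)) return()
    if (!mol_connected(newmol) || n_heavy(newmol) == 0L) return()
    if (!check_valences(newmol)) return()
    newmol <- with_key(newmol)
    if (!nzchar(newmol$key)) return()   # unsanitizable: discard
    out[[length(out) + 1L]] <<- list(mol = newmol, map = newmap, proc = proc)
  }

  core <- which(!is.na(map))
  # settled atoms already agree with their target partner in element and
  # charge; everything else (non-core atoms and mismatched core atoms) still
  # has to change and is fair game for the deletion procedures
  settled <- rep(FALSE, n_heavy(mol))
  settled[core] <- mol$elem[core] == target$elem[map[core]] &
    mol$charge[core] == target$charge[map[core]]

  # (a) mutate core atoms toward their mapped target atoms (element + charge)
  for (i in core[!settled[core]]) {
    t <- map[i]
    emit(set_atom(mol, i, target$elem[t], target$charge[t]), map, "a")
  }

  # (b) delete one acyclic unsettled atom if the graph stays connected
  for (i in which(!settled)) {
    if (mol$ring_atom[i]) next
    d <- delete_atoms(mol, i)
    if (mol_connected(d$mol)) emit(d$mol, map[d$survivors], "b")
  }

  rs <- ring_systems(mol)
  rings <- chordless_rings(mol)
  for (S in rs) {
    if (all(!settled[S])) {
      # (c)/(d): whole ring system outside the core, attached by one bond
      ext <- which(xor(mol$bond[, 1L] %in% S, mol$bond[, 2L] %in% S))
      if (length(ext) == 1L) {
        eb <- mol$bond[ext, ]
        att <- if (eb[1L] %in% S) eb[2L] else eb[1L]
        d <- delete_atoms(mol, S)
        if (mol_connected(d$mol)) {
          emit(d$mol, map[d$survivors], "c")
          att_new <- match(att, d$survivors)
          emit(add_atom(d$mol, "C", 0L, att_new), c(map[d$survivors], NA), "d")
        }
      }
    }
    # (e): peel one ring off a fused system: delete the atoms exclusive to a
    # single ring when none of them is matched to the target core
    ringsS <- rings[vapply(rings, function(r) all(r %in% S), TRUE)]
    if (length(ringsS) < 2L) next
    for (ri in seq_along(ringsS)) {
      R <- ringsS[[ri]]
      shared <- unique(unlist(ringsS[-ri]))
      excl <- setdiff(R, shared)
      if (!length(excl) || any(!is.na(map[excl]))) next
      d <- delete_atoms(mol, excl)
      if (!mol_connected(d$mol)) next
      keptS <- match(setdiff(S, excl), d$survivors)
      fixed <- rekekulize(d$mol, keptS)
      emit(fixed, map[d$survivors], "e")
    }
  }
  out
}

# --- compound records --------------------------------------------------------

#' Create a compound record
#'
#' A molecule plus its role in a run and, for generated intermediates, the
#' provenance of the edit that produced it.
#'
#' @param mol A `molgraph`, SMILES string, or existing record.
#' @param id Unique identifier within the run.
#' @param role One of `"input_A"`, `"input_B"`, `"intermediate"`,
#'   `"series_member"`.
#' @param provenance List of `list(proc, parent)` entries (empty for inputs).
#' @param direction `"from_A"`, `"from_B"` or `"none"`.
#' @return Object of class `compound_record`.
#' @export
compound_record <- function(mol, id, role = c("input_A", "input_B",
                                              "intermediate", "series_member"),
                            provenance = list(), direction = "none") {
  role <- match.arg(role)
  mol <- .as_molgraph(mol)
  mol <- with_key(mol)
  structure(list(id = id, mol = mol, role = role, key = mol$key,
                 provenance = provenance, direction = direction),
            class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<%s> %s  %s  (%s)\n", x$role, x$id, x$key, x$direction))
  invisible(x)
}

# --- directed closure --------------------------------------------------------

#' Generate all intermediates from one compound toward a target's core frame
#'
#' Breadth-style closure of [enumerate_edits()] driven by a LIFO compound
#' pool with global canonical-key deduplication: final compounds match the
#' common core shared with `target`. Inputs with a different net charge than
#' the start are discarded along the way (charge-changing intermediates incur
#' extra simulation cost and are excluded by design).
#'
#' @param start A `compound_record` (the starting ligand).
#' @param target A `compound_record` (the ligand whose core is approached).
#' @param mcs An `mcs_mapping` between `start` and `target` molecules (in
#'   that order); computed if `NULL`.
#' @param direction Label stored on generated records.
#' @param visited Optional environment of already-seen canonical keys shared
#'   between the two generation directions.
#' @param max_pops,max_candidates Safety caps; exceeding either aborts.
#' @return Named list of intermediate `compound_record`s (excluding `start`).
#' @export
generate_directed <- function(start, target, mcs = NULL, direction = "from_A",
                              visited = NULL, max_pops = 50000L,
                              max_candidates = 10000L) {
  stopifnot(inherits(start, "compound_record"), inherits(target, "compound_record"))
  if (is.null(mcs)) mcs <- compute_mcs(start$mol, target$mol)
  if (is.null(visited)) visited <- new.env(parent = emptyenv())
  charge0 <- net_charge(start$mol)

  map0 <- rep(NA_integer_, n_heavy(start$mol))
  map0[mcs$pairs[, 1L]] <- mcs$pairs[, 2L]

  assign(start$key, TRUE, envir = visited)
  pool <- list(list(mol = start$mol, map = map0, parent = start$id))
  out <- list()
  pops <- 0L
  while (length(pool)) {
    pops <- pops + 1L
    if (pops > max_pops)
      stop("intermediate generation exceeded the pool-pop cap; inputs too combinatorial")
    state <- pool[[length(pool)]]
    pool[[length(pool)]] <- NULL
    edits <- enumerate_edits(state$mol, target$mol, state$map)
    for (ed in edits) {
      key <- ed$mol$key
      if (net_charge(ed$mol) != charge0) next       # charge filter
      if (!is.null(visited[[key]])) next
      assign(key, TRUE, envir = visited)
      id <- sprintf("%s%03d", if (direction == "from_A") "ia" else "ib",
                    length(out) + 1L)
      rec <- compound_record(ed$mol, id, "intermediate",
                             provenance = list(list(proc = ed$proc,
                                                    parent = state$parent)),
                             direction = direction)
      out[[id]] <- rec
      if (length(out) > max_candidates)
        stop("intermediate generation exceeded the candidate cap")
      pool[[length(pool) + 1L]] <- list(mol = ed$mol, map = ed$map, parent = id)
    }
  }
  attr(out, "pops") <- pops
  out
}

# --- bidirectional generation ------------------------------------------------

#' Exhaustively generate intermediates between two ligands
#'
#' Runs the directed closure in both directions (A toward B's core frame and
#' B toward A's), deduplicates across directions by canonical key, and
#' returns the combined candidate set including the inputs themselves. The
#' two inputs must carry the same net charge; all intermediates share it.
#'
#' @param ligand_a,ligand_b `compound_record`s, `molgraph`s, or SMILES.
#' @param timeout MCS time budget (seconds) for the input pair.
#' @param max_pops,max_candidates Safety caps per direction.
#' @return Object of class `generation_result`: named list `records`, input
#'   ids `a_id`/`b_id`, the input `mcs_ab`, and per-procedure `stats`.
#' @examples
#' gen <- exhaustive_generate("c1ccc(-c2ccccc2)cc1", "Oc1ccccc1")
#' length(gen$records)
#' @export
exhaustive_generate <- function(ligand_a, ligand_b, timeout = 10,
                                max_pops = 50000L, max_candidates = 10000L) {
  a <- if (inherits(ligand_a, "compound_record")) ligand_a else
    compound_record(ligand_a, "A", "input_A")
  b <- if (inherits(ligand_b, "compound_record")) ligand_b else
    compound_record(ligand_b, "B", "input_B")
  a$role <- "input_A"; b$role <- "input_B"
  if (net_charge(a$mol) != net_charge(b$mol))
    stop(sprintf("net charges differ (%+d vs %+d); input ligands must share a net charge",
                 net_charge(a$mol), net_charge(b$mol)))

  records <- list()
  records[[a$id]] <- a
  if (b$key == a$key) {
    # identical inputs collapse to a single node
    res <- structure(list(records = records, a_id = a$id, b_id = a$id,
                          mcs_ab = compute_mcs(a$mol, b$mol),
                          stats = c(a = 0L, b = 0L, c = 0L, d = 0L, e = 0L)),
                     class = "generation_result")
    return(res)
  }
  records[[b$id]] <- b

  mcs_ab <- compute_mcs(a$mol, b$mol, timeout = timeout)
  visited <- new.env(parent = emptyenv())
  assign(a$key, TRUE, envir = visited)
  assign(b$key, TRUE, envir = visited)

  dir_a <- generate_directed(a, b, mcs = mcs_ab, direction = "from_A",
                             visited = visited, max_pops = max_pops,
                             max_candidates = max_candidates)
  mcs_ba <- structure(list(pairs = mcs_ab$pairs[, c(2L, 1L), drop = FALSE],
                           n_mcs = mcs_ab$n_mcs,
                           mismatched_pairs = mcs_ab$mismatched_pairs[, c(2L, 1L), drop = FALSE],
                           timed_out = mcs_ab$timed_out),
                      class = "mcs_mapping")
  colnames(mcs_ba$pairs) <- c("a", "b")
  dir_b <- generate_directed(b, a, mcs = mcs_ba, direction = "from_B",
                             visited = visited, max_pops = max_pops,
                             max_candidates = max_candidates)

  inter <- c(dir_a, dir_b)
  ids <- sprintf("I%03d", seq_along(inter))
  stats <- c(a = 0L, b = 0L, c = 0L, d = 0L, e = 0L)
  old2new <- stats::setNames(ids, names(inter))
  for (k in seq_along(inter)) {
    rec <- inter[[k]]
    rec$provenance <- lapply(rec$provenance, function(p) {
      if (p$parent %in% names(old2new)) p$parent <- unname(old2new[p$parent])
      p
    })
    stats[rec$provenance[[1L]]$proc] <- stats[rec$provenance[[1L]]$proc] + 1L
    rec$id <- ids[k]
    records[[rec$id]] <- rec
  }
  structure(list(records = records, a_id = a$id, b_id = b$id,
                 mcs_ab = mcs_ab, stats = stats),
            class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat(sprintf("<generation_result> %d compounds (%d intermediates) between %s and %s\n",
              length(x$records), length(x$records) - length(unique(c(x$a_id, x$b_id))),
              x$a_id, x$b_id))
  cat("  per procedure:", paste(names(x$stats), x$stats, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Export a candidate set as SDF or SMILES with provenance tags
#'
#' @param gen A `generation_result`.
#' @param path Output path; `.sdf` writes a multi-record SDF whose records
#'   carry `role`, `procedure` and `parent` properties, anything else a
#'   SMILES list.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(gen, path) {
  mols <- lapply(gen$records, function(r) r$mol)
  if (tolower(tools::file_ext(path)) == "sdf") {
    props <- lapply(gen$records, function(r) {
      list(role = r$role,
           procedure = if (length(r$provenance)) r$provenance[[1L]]$proc else "",
           parent = if (length(r$provenance)) r$provenance[[1L]]$parent else "")
    })
    write_sdf(mols, path, properties = props)
  } else {
    write_smiles_file(mols, path)
  }
  invisible(path)
}
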