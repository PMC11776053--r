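# Protonation-state assignment -------------------------------------------------
#
# A small deterministic rule table standing in for a full ligand-preparation
# pipeline: ionizable groups that are essentially fully charged at
# physiological pH (7.4) are set to their dominant microstate. Explicit
# charges present in the input are preserved; rules only touch neutral
# matching groups. The table is intentionally conservative - absolute
# protonation states from a commercial preparation tool may differ.

.atom_degree <- function(mol) {
  d <- integer(n_heavy(mol))
  for (k in seq_len(nrow(mol$bond))) {
    d[mol$bond[k, 1L]] <- d[mol$bond[k, 1L]] + 1L
    d[mol$bond[k, 2L]] <- d[mol$bond[k, 2L]] + 1L
  }
  d
}

.neighbors_of <- function(mol, i) {
  b <- mol$bond
  c(b[b[, 1L] == i, 2L], b[b[, 2L] == i, 1L])
}

.bond_order_between <- function(mol, i, j) {
  b <- mol$bond
  hit <- (b[, 1L] == i & b[, 2L] == j) | (b[, 1L] == j & b[, 2L] == i)
  if (any(hit)) b[hit, 3L][1L] else 0L
}

#' Assign formal charges by fixed protonation rules
#'
#' Applies a deterministic rule table at pH 7.4: carboxylic and sulfonic
#' acid hydroxyls are deprotonated (O gets charge -1) and aliphatic
#' (sp3, non-aromatic, non-amide) amines are protonated (N gets +1).
#' Atoms already carrying explicit charges are left untouched.
#'
#' @param mol A `molgraph`.
#' @return The adjusted `molgraph` (re-keyed).
#' @examples
#' net_charge(assign_net_charge(parse_structure("CC(=O)O")))  # -1
#' @export
assign_net_charge <- function(mol) {
  stopifnot(is_molgraph(mol))
  deg <- .atom_degree(mol)
  charge <- mol$charge
  for (i in seq_len(n_heavy(mol))) {
    if (charge[i] != 0L) next
    el <- mol$elem[i]
    nb <- .neighbors_of(mol, i)
    if (el == "O" && deg[i] == 1L && .bond_order_between(mol, i, nb[1L]) == 1L) {
      # hydroxyl O on a carboxylic (C(=O)OH) or sulfonic (S(=O)(=O)OH) acid
      ctr <- nb[1L]
      dbl_o <- sum(vapply(.neighbors_of(mol, ctr), function(j)
        mol$elem[j] == "O" && .bond_order_between(mol, ctr, j) == 2L, TRUE))
      if ((mol$elem[ctr] == "C" && dbl_o >= 1L) ||
          (mol$elem[ctr] == "S" && dbl_o >= 2L))
        charge[i] <- -1L
    } else if (el == "N" && !mol$aromatic[i] && deg[i] <= 3L) {
      # aliphatic amine: all single bonds, no carbonyl/imine neighbor (amide,
      # amidine, aniline-type N excluded)
      orders <- vapply(nb, function(j) .bond_order_between(mol, i, j), 0L)
      if (length(orders) && all(orders == 1L)) {
        conj <- any(vapply(nb, function(j) {
          mol$aromatic[j] ||
            any(vapply(.neighbors_of(mol, j), function(k)
              k != i && mol$elem[k] %in% c("O", "N", "S") &&
                .bond_order_between(mol, j, k) == 2L, TRUE))
        }, TRUE))
        if (!conj) charge[i] <- 1L
      }
    }
  }
  out <- new_molgraph(mol$elem, charge, mol$aromatic, mol$bond)
  with_key(out)
}
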