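# Molecular graphs -----------------------------------------------------------
#
# Molecules are stored hydrogen-suppressed and kekulized: only heavy atoms,
# bond orders in {1, 2, 3}. Aromaticity is kept as a per-atom flag (taken from
# the canonical SMILES at parse time) so that ring-deletion edits can restore
# an alternating bond pattern; it never enters bond orders. Open Babel (via
# ChemmineOB) is the format layer and canonicalizer, but it is deliberately
# lenient about valence, so chemical sanity is enforced here.

#' Construct a molecular graph
#'
#' Low-level constructor used by the parsers and the edit machinery. Most
#' users should call [parse_structure()] instead.
#'
#' @param elem Character vector of element symbols, one per heavy atom.
#' @param charge Integer vector of formal charges (elementary charge units).
#' @param aromatic Logical vector flagging atoms that belong to an aromatic
#'   system in the canonical form of the molecule.
#' @param bond Integer matrix with columns `i`, `j`, `order`; orders must be
#'   1, 2 or 3 (the representation is kekulized).
#' @param key Canonical SMILES if already known, else `NULL` (computed lazily
#'   by [canonical_key()]).
#' @return An object of class `molgraph`.
#' @keywords internal
new_molgraph <- function(elem, charge, aromatic, bond, key = NULL) {
  n <- length(elem)
  stopifnot(length(charge) == n, length(aromatic) == n)
  if (is.null(bond) || NROW(bond) == 0L) {
    bond <- matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("i", "j", "order")))
  } else {
    bond <- matrix(as.integer(bond), ncol = 3L, dimnames = list(NULL, c("i", "j", "order")))
    swap <- bond[, 1L] > bond[, 2L]
    bond[swap, 1:2] <- bond[swap, 2:1]
    bond <- bond[order(bond[, 1L], bond[, 2L]), , drop = FALSE]
    if (any(bond[, 3L] < 1L | bond[, 3L] > 3L))
      stop("bond orders must be 1, 2 or 3 (kekulized representation)")
  }
  mol <- structure(
    list(elem = as.character(elem), charge = as.integer(charge),
         aromatic = as.logical(aromatic), bond = bond, key = key),
    class = "molgraph")
  ring <- .ring_flags(mol)
  mol$ring_bond <- ring$bond
  mol$ring_atom <- ring$atom
  mol
}

# ring bonds = edges on some cycle = non-bridge edges
.ring_flags <- function(mol) {
  n <- length(mol$elem)
  nb <- nrow(mol$bond)
  if (nb == 0L) return(list(bond = logical(0), atom = rep(FALSE, n)))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(mol$bond[, 1:2, drop = FALSE]))
  br <- as.integer(igraph::bridges(g))
  ring_bond <- !(seq_len(nb) %in% br)
  atom <- rep(FALSE, n)
  if (any(ring_bond)) atom[unique(as.vector(mol$bond[ring_bond, 1:2]))] <- TRUE
  list(bond = ring_bond, atom = atom)
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d heavy atoms, %d bonds, net charge %+d\n",
              n_heavy(x), nrow(x$bond), net_charge(x)))
  cat("  ", canonical_key(x), "\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms
#' @param mol A `molgraph`.
#' @return Integer heavy-atom count (hydrogens are implicit and never counted).
#' @export
n_heavy <- function(mol) length(mol$elem)

#' Net formal charge
#' @param mol A `molgraph`.
#' @return Integer sum of formal charges.
#' @export
net_charge <- function(mol) sum(mol$charge)

is_molgraph <- function(x) inherits(x, "molgraph")

mol_graph_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n_heavy(mol), directed = FALSE)
  if (nrow(mol$bond)) g <- igraph::add_edges(g, t(mol$bond[, 1:2, drop = FALSE]))
  g
}

mol_connected <- function(mol) {
  n <- n_heavy(mol)
  if (n <= 1L) return(TRUE)
  igraph::is_connected(mol_graph_igraph(mol))
}

# Open Babel glue -------------------------------------------------------------

ob_convert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, source = text),
                  error = function(e) "")
  out
}

# canonical SMILES of a single record; "" on failure
ob_canonical <- function(from, text) {
  out <- ob_convert(from, "CAN", text)
  if (!nzchar(out)) return("")
  out <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  trimws(sub("\t.*$", "", out))
}

# Maximum allowed bond-order sum per neutral element; formal charge shifts the
# cap (+q for N/P/O/S/halogens, -|q| for C/Si). This is a sanity filter for
# edit products, not a full valence model.
.MAX_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                  P = 5, S = 6, Cl = 1, Br = 1, I = 1)

atom_valence_cap <- function(elem, charge) {
  base <- unname(.MAX_VALENCE[elem])
  base[is.na(base)] <- 6  # unusual elements: be permissive
  cap <- ifelse(elem %in% c("C", "Si"), base - abs(charge), base + charge)
  pmax(cap, 0)
}

check_valences <- function(mol) {
  n <- n_heavy(mol)
  bsum <- numeric(n)
  if (nrow(mol$bond)) {
    for (k in seq_len(nrow(mol$bond))) {
      bsum[mol$bond[k, 1L]] <- bsum[mol$bond[k, 1L]] + mol$bond[k, 3L]
      bsum[mol$bond[k, 2L]] <- bsum[mol$bond[k, 2L]] + mol$bond[k, 3L]
    }
  }
  all(bsum <= atom_valence_cap(mol$elem, mol$charge))
}

# V2000 molblock I/O ----------------------------------------------------------
# Only the fields this package uses are read/written (element, connectivity,
# order, M CHG). All geometry is zeroed; the planner is 2D/3D-agnostic.

write_molblock <- function(mol) {
  n <- n_heavy(mol)
  nb <- nrow(mol$bond)
  lines <- c("", " alchemap", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  lines <- c(lines, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, mol$elem))
  if (nb) lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                    mol$bond[, 1L], mol$bond[, 2L], mol$bond[, 3L]))
  chg <- which(mol$charge != 0L)
  while (length(chg)) {
    take <- chg[seq_len(min(8L, length(chg)))]
    chg <- chg[-seq_along(take)]
    lines <- c(lines, paste0(sprintf("M  CHG%3d", length(take)),
                             paste0(sprintf("%4d%4d", take, mol$charge[take]), collapse = "")))
  }
  paste0(paste(c(lines, "M  END", "$$$$"), collapse = "\n"), "\n")
}

read_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("truncated molblock")
  n <- as.integer(substr(lines[4L], 1L, 3L))
  nb <- as.integer(substr(lines[4L], 4L, 6L))
  if (is.na(n) || is.na(nb)) stop("unreadable molblock counts line")
  at <- lines[4L + seq_len(n)]
  elem <- trimws(substr(at, 32L, 34L))
  bd <- lines[4L + n + seq_len(nb)]
  bond <- cbind(i = as.integer(substr(bd, 1L, 3L)),
                j = as.integer(substr(bd, 4L, 6L)),
                order = as.integer(substr(bd, 7L, 9L)))
  charge <- rep(0L, n)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- scan(text = sub("^M  CHG", "", ln), what = integer(), quiet = TRUE)
    cnt <- toks[1L]
    for (k in seq_len(cnt)) charge[toks[2L * k]] <- toks[2L * k + 1L]
  }
  list(elem = elem, charge = charge, bond = bond)
}

# Aromatic atom flags from a SMILES string, in atom order. Open Babel keeps
# SMILES atom order when converting to SDF, so these flags line up with the
# molblock atoms.
smiles_aromatic_flags <- function(smi) {
  flags <- logical(0)
  chars <- strsplit(smi, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      content <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      sym <- regmatches(content, regexpr("[A-Za-z]", content))
      flags <- c(flags, length(sym) == 1L && sym %in% c("b", "c", "n", "o", "p", "s"))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < length(chars) && chars[i + 1L] %in% c("l", "r")) {
      flags <- c(flags, FALSE)  # Cl / Br
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      flags <- c(flags, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      flags <- c(flags, TRUE)
      i <- i + 1L
    } else {
      i <- i + 1L  # digits, bonds, branches, ring-closure marks, '.'
    }
  }
  flags
}

# Parsing ---------------------------------------------------------------------

#' Parse a molecule from SMILES or an SDF record
#'
#' Input is round-tripped through Open Babel's canonical SMILES, which both
#' validates the syntax and fixes a canonical atom order; the returned graph
#' is hydrogen-suppressed and kekulized. Multi-fragment (disconnected) input
#' is rejected: the planner works on single molecules.
#'
#' @param text A SMILES string or the text of one SDF (V2000) record.
#' @param format `"smiles"` or `"sdf"`.
#' @param name Optional record name used in error messages.
#' @return A `molgraph`.
#' @examples
#' benzene <- parse_structure("c1ccccc1")
#' n_heavy(benzene)   # 6
#' @export
parse_structure <- function(text, format = c("smiles", "sdf"), name = NULL) {
  format <- match.arg(format)
  label <- if (is.null(name)) substr(trimws(text)[1], 1, 40) else name
  can <- switch(format,
    smiles = ob_canonical("SMI", text),
    sdf    = ob_canonical("SDF", text))
  if (!nzchar(can))
    stop(sprintf("could not parse %s record '%s'", format, label))
  if (grepl(".", can, fixed = TRUE))
    stop(sprintf("record '%s' contains multiple fragments; supply a single connected molecule", label))
  mol_from_canonical_smiles(can, label)
}

mol_from_canonical_smiles <- function(can, label = can) {
  sdf <- ob_convert("SMI", "SDF", can)
  if (!nzchar(sdf)) stop(sprintf("conversion failed for '%s'", label))
  mb <- read_molblock(sdf)
  arom <- smiles_aromatic_flags(can)
  if (length(arom) != length(mb$elem))
    stop(sprintf("atom bookkeeping mismatch for '%s'", label))
  mol <- new_molgraph(mb$elem, mb$charge, arom, mb$bond, key = can)
  if (!mol_connected(mol))
    stop(sprintf("record '%s' is disconnected", label))
  if (!check_valences(mol))
    stop(sprintf("record '%s' has a chemically impossible valence", label))
  mol
}

#' Canonical structure key
#'
#' Canonical SMILES (Open Babel) of a molecular graph, invariant under atom
#' reordering; used throughout for deduplication of generated intermediates.
#'
#' @param mol A `molgraph`.
#' @return Canonical SMILES string.
#' @export
canonical_key <- function(mol) {
  stopifnot(is_molgraph(mol))
  if (!is.null(mol$key)) return(mol$key)
  key <- ob_canonical("SDF", write_molblock(mol))
  if (!nzchar(key)) stop("canonicalization failed")
  key
}

# Return mol with its key slot filled; "" key signals an unsanitizable graph.
with_key <- function(mol) {
  if (is.null(mol$key)) mol$key <- ob_canonical("SDF", write_molblock(mol))
  mol
}

#' Write molecules as canonical SMILES
#' @param mol A `molgraph`.
#' @return A SMILES string.
#' @export
to_smiles <- function(mol) canonical_key(mol)

# apply an atom permutation: atom k of the result is atom perm[k] of the input
permute_molgraph <- function(mol, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  bond <- mol$bond
  bond[, 1L] <- inv[bond[, 1L]]
  bond[, 2L] <- inv[bond[, 2L]]
  new_molgraph(mol$elem[perm], mol$charge[perm], mol$aromatic[perm], bond)
}

# File readers/writers --------------------------------------------------------

#' Read ligands from a SMILES list or multi-record SDF file
#'
#' SMILES files hold one molecule per line with an optional whitespace
#' separated name; SDF files are split on `$$$$` record terminators, with the
#' record title line used as the name.
#'
#' @param path File path; format is inferred from the extension (`.smi`,
#'   `.smiles`, `.txt` vs `.sdf`, `.mol`) unless `format` is given.
#' @param format Optional `"smiles"` or `"sdf"` override.
#' @return A named list of `molgraph` objects.
#' @export
read_ligands <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sdf", "mol", "mdl")) "sdf" else "smiles"
  }
  lines <- readLines(path, warn = FALSE)
  out <- list()
  if (format == "smiles") {
    lines <- lines[nzchar(trimws(lines))]
    for (k in seq_along(lines)) {
      toks <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
      nm <- if (length(toks) >= 2L) toks[2L] else sprintf("mol%02d", k)
      out[[nm]] <- parse_structure(toks[1L], "smiles", name = nm)
    }
  } else {
    recs <- split(lines, cumsum(c(0L, utils::head(grepl("^\\$\\$\\$\\$", lines), -1L))))
    k <- 0L
    for (rec in recs) {
      if (!any(grepl("M  END", rec, fixed = TRUE))) next
      k <- k + 1L
      nm <- trimws(rec[1L])
      if (!nzchar(nm)) nm <- sprintf("mol%02d", k)
      out[[nm]] <- parse_structure(paste(rec, collapse = "\n"), "sdf", name = nm)
    }
    if (k == 0L) stop(sprintf("no SDF records found in '%s'", path))
  }
  out
}

#' Write molecules to a multi-record SDF file
#'
#' @param mols Named list of `molgraph` objects (names become record titles).
#' @param path Output file.
#' @param properties Optional named list (per molecule) of record properties
#'   written as `> <tag>` data items.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, properties = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(mols)) {
    block <- write_molblock(mols[[nm]])
    block <- sub("^\n alchemap", paste0(nm, "\n alchemap"), block)
    block <- sub("\\$\\$\\$\\$\n$", "", block)
    writeLines(sub("\n$", "", block), con)
    props <- properties[[nm]]
    for (tag in names(props)) {
      writeLines(sprintf("> <%s>", tag), con)
      writeLines(as.character(props[[tag]]), con)
      writeLines("", con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Write molecules as a SMILES list
#' @param mols Named list of `molgraph` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(mols, path) {
  writeLines(sprintf("%s\t%s", vapply(mols, canonical_key, ""), names(mols)), path)
  invisible(path)
}
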