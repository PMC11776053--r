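# molecular graph parsing, canonicalization, and MCS

test_that("parsing yields hydrogen-suppressed graphs with correct counts and charges", {
  expect_equal(n_heavy(fix_mol("benzene")), 6L)
  expect_equal(net_charge(fix_mol("benzene")), 0L)
  expect_equal(n_heavy(fix_mol("toluene")), 7L)
  # formal charges summed from an independent hand count: acetate carries one
  # deprotonated oxygen
  expect_equal(net_charge(fix_mol("acetate")), -1L)
  expect_equal(n_heavy(fix_mol("acetate")), 4L)
})

test_that("parse failures and disconnected input are rejected with diagnostics", {
  expect_error(parse_structure("C1CC"), "could not parse")
  expect_error(parse_structure("CC.O"), "multiple fragments")
  expect_error(parse_structure("not a molecule", name = "rec7"), "rec7")
})

test_that("canonical keys identify molecules irrespective of encoding or atom order", {
  expect_identical(canonical_key(parse_structure("C1=CC=CC=C1")),
                   canonical_key(fix_mol("benzene")))
  expect_false(canonical_key(fix_mol("toluene")) == canonical_key(fix_mol("benzene")))
  # permutation oracle: keys of randomly re-ordered atom lists all agree
  permute <- function(mol, perm) alchemap:::permute_molgraph(mol, perm)
  for (nm in c("toluene", "acetate", "naphthalene")) {
    mol <- fix_mol(nm)
    ref <- canonical_key(mol)
    set.seed(42)
    for (k in 1:25) {
      perm <- sample(n_heavy(mol))
      expect_identical(canonical_key(permute(mol, perm)), ref)
    }
  }
})

test_that("canonical keys separate distinct constitutions on the fixture set", {
  keys <- vapply(names(SMI), function(nm) canonical_key(fix_mol(nm)), "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("MCS matches the exhaustive oracle on small pairs", {
  cases <- list(
    list("benzene", "benzene", TRUE),
    list("toluene", "phenol", TRUE),
    list("toluene", "phenol", FALSE),
    list("benzene", "pyridine", TRUE),
    list("benzene", "pyridine", FALSE),
    list("toluene", "benzene", TRUE),
    list("propane", "ethane", TRUE),
    list("methane", "benzene", TRUE),
    list("acetate", "propane", FALSE),
    list("ethylamine", "propane", TRUE))
  for (cs in cases) {
    a <- fix_mol(cs[[1]]); b <- fix_mol(cs[[2]])
    got <- compute_mcs(a, b, allow_element_mismatch = cs[[3]])
    expect_equal(got$n_mcs, oracle_mcs_size(a, b, cs[[3]]),
                 info = sprintf("%s/%s mismatch=%s", cs[[1]], cs[[2]], cs[[3]]))
  }
})

test_that("the toluene/phenol MCS pairs the methyl carbon with the hydroxyl oxygen", {
  m <- compute_mcs(fix_mol("toluene"), fix_mol("phenol"))
  expect_equal(m$n_mcs, 7L)
  expect_equal(nrow(m$mismatched_pairs), 1L)
  i <- m$mismatched_pairs[1, 1]; j <- m$mismatched_pairs[1, 2]
  expect_equal(fix_mol("toluene")$elem[i], "C")
  expect_equal(fix_mol("phenol")$elem[j], "O")
  strict <- compute_mcs(fix_mol("toluene"), fix_mol("phenol"),
                        allow_element_mismatch = FALSE)
  expect_equal(strict$n_mcs, 6L)
})

test_that("MCS size is symmetric, maximal on identity, and monotone in matching strictness", {
  mols <- lapply(c("benzene", "toluene", "phenol", "pyridine", "propane",
                   "acetate", "naphthalene"), fix_mol)
  for (a in mols) {
    expect_equal(compute_mcs(a, a)$n_mcs, n_heavy(a))
    for (b in mols) {
      loose <- compute_mcs(a, b, TRUE)
      tight <- compute_mcs(a, b, FALSE)
      expect_equal(loose$n_mcs, compute_mcs(b, a, TRUE)$n_mcs)
      expect_lte(tight$n_mcs, loose$n_mcs)
      expect_lte(loose$n_mcs, min(n_heavy(a), n_heavy(b)))
      # one-to-one in both directions, induced isomorphism on ring bonds
      expect_equal(anyDuplicated(loose$pairs[, 1]), 0L)
      expect_equal(anyDuplicated(loose$pairs[, 2]), 0L)
    }
  }
})

test_that("SMILES and SDF files round-trip through the readers and writers", {
  mols <- list(b = fix_mol("benzene"), t = fix_mol("toluene"),
               a = fix_mol("acetate"))
  smi <- withr::local_tempfile(fileext = ".smi")
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_smiles_file(mols, smi)
  write_sdf(mols, sdf)
  keys <- vapply(mols, canonical_key, "")
  expect_identical(vapply(read_ligands(smi), canonical_key, ""), keys)
  expect_identical(vapply(read_ligands(sdf), canonical_key, ""), keys)
})

test_that("protonation rules set expected charges and preserve explicit ones", {
  expect_equal(net_charge(assign_net_charge(parse_structure("CCCC"))), 0L)
  expect_equal(net_charge(assign_net_charge(parse_structure("CC(=O)O"))), -1L)
  expect_equal(net_charge(assign_net_charge(fix_mol("ethylamine"))), 1L)
  # amide nitrogen and aromatic rings stay neutral
  expect_equal(net_charge(assign_net_charge(parse_structure("CC(=O)NC"))), 0L)
  expect_equal(net_charge(assign_net_charge(fix_mol("pyridine"))), 0L)
  expect_equal(net_charge(assign_net_charge(parse_structure("Nc1ccccc1"))), 0L)
  # an explicit charge is preserved while rules still act on neutral groups
  mol <- assign_net_charge(parse_structure("[NH3+]CCC(=O)O"))
  expect_equal(net_charge(mol), 0L)
  expect_equal(sum(mol$charge == 1L), 1L)
  expect_equal(sum(mol$charge == -1L), 1L)
})
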