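# intermediate enumeration and the compound-pool closure

mcs_map_of <- function(a, b) {
  m <- compute_mcs(a, b)
  map <- rep(NA_integer_, n_heavy(a))
  map[m$pairs[, 1]] <- m$pairs[, 2]
  map
}

test_that("single edits reproduce the worked examples", {
  tol <- fix_mol("toluene"); phe <- fix_mol("phenol")
  ed <- enumerate_edits(tol, phe, mcs_map_of(tol, phe))
  keys <- vapply(ed, function(e) e$mol$key, "")
  expect_true(canonical_key(phe) %in% keys[vapply(ed, `[[`, "", "proc") == "a"])

  bip <- fix_mol("biphenyl"); ben <- fix_mol("benzene")
  ed2 <- enumerate_edits(bip, ben, mcs_map_of(bip, ben))
  got <- setNames(vapply(ed2, function(e) e$mol$key, ""),
                  vapply(ed2, `[[`, "", "proc"))
  expect_setequal(names(got), c("c", "d"))
  expect_equal(unname(got["c"]), canonical_key(ben))
  expect_equal(unname(got["d"]), canonical_key(fix_mol("toluene")))

  # nothing outside the core and nothing mismatched: no edits at all
  expect_length(enumerate_edits(ben, ben, mcs_map_of(ben, ben)), 0L)
})

test_that("fused-ring peeling shrinks a naphthalene to its shared ring", {
  nap <- fix_mol("naphthalene"); ben <- fix_mol("benzene")
  ed <- enumerate_edits(nap, ben, mcs_map_of(nap, ben))
  expect_true(canonical_key(ben) %in% vapply(ed, function(e) e$mol$key, ""))
  expect_true("e" %in% vapply(ed, `[[`, "", "proc"))
})

test_that("identical inputs collapse to a single compound", {
  gen <- exhaustive_generate(fix_mol("benzene"), fix_mol("benzene"))
  expect_length(gen$records, 1L)
  expect_identical(gen$a_id, gen$b_id)
})

test_that("the biphenyl/phenol closure contains the manually enumerated intermediates", {
  gen <- exhaustive_generate(fix_mol("biphenyl"), fix_mol("phenol"))
  keys <- vapply(gen$records, function(r) r$key, "")
  expect_true(all(c(canonical_key(fix_mol("biphenyl")), canonical_key(fix_mol("phenol")),
                    canonical_key(fix_mol("benzene")), canonical_key(fix_mol("toluene")))
                  %in% keys))
})

test_that("inputs with different net charges are rejected before generation", {
  expect_error(exhaustive_generate(fix_mol("acetate"), fix_mol("benzene")),
               "net charges differ")
})

test_that("candidates are charge-matched, deduplicated, and provenance-reachable", {
  pairs <- list(c("biphenyl", "phenol"), c("naphthalene", "toluene"),
                c("biphenyl", "pyridine"))
  for (p in pairs) {
    gen <- exhaustive_generate(fix_mol(p[1]), fix_mol(p[2]))
    keys <- vapply(gen$records, function(r) r$key, "")
    expect_equal(anyDuplicated(keys), 0L)
    charges <- vapply(gen$records, function(r) net_charge(r$mol), 0L)
    expect_true(all(charges == net_charge(fix_mol(p[1]))))
    # every intermediate's provenance chain walks back to an input
    ids <- names(gen$records)
    for (r in gen$records) {
      if (r$role != "intermediate") next
      expect_gt(length(r$provenance), 0L)
      cur <- r
      for (step in 1:50) {
        parent <- cur$provenance[[1]]$parent
        expect_true(parent %in% ids)
        cur <- gen$records[[parent]]
        if (cur$role != "intermediate") break
      }
      expect_true(cur$role %in% c("input_A", "input_B"))
    }
  }
})

test_that("generation is deterministic across runs", {
  g1 <- exhaustive_generate(fix_mol("biphenyl"), fix_mol("phenol"))
  g2 <- exhaustive_generate(fix_mol("biphenyl"), fix_mol("phenol"))
  expect_identical(sort(vapply(g1$records, function(r) r$key, "")),
                   sort(vapply(g2$records, function(r) r$key, "")))
  expect_identical(g1$stats, g2$stats)
})

test_that("candidate sets export with provenance tags", {
  gen <- exhaustive_generate(fix_mol("biphenyl"), fix_mol("phenol"))
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_candidates(gen, sdf)
  back <- read_ligands(sdf)
  expect_setequal(unname(vapply(back, canonical_key, "")),
                  unname(vapply(gen$records, function(r) r$key, "")))
  expect_true(any(grepl("> <procedure>", readLines(sdf), fixed = TRUE)))
})
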