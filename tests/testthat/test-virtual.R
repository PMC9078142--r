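test_that("fragment library equals a brute-force enumeration of donor cuts", {
  donors <- fixture_molecules(10, seed = 13)
  lib <- build_fragment_library(donors)
  # oracle: collect the substituent side of every single cut, deduplicate
  cuts <- recap_single_cut(donors)
  oracle <- sort(unique(cuts$substituent[cuts$sub_n_heavy <= 13]))
  expect_identical(lib$fragments$fragment, oracle)
  expect_identical(lib$source_count, 10L)
  expect_identical(lib$excluded_count, 0L)
})

test_that("exclusion removes observed substituents with set semantics", {
  donors <- fixture_molecules(10, seed = 13)
  all_lib <- build_fragment_library(donors)
  excl <- all_lib$fragments$fragment
  none <- build_fragment_library(donors, exclusion = excl)
  expect_identical(nrow(none$fragments), 0L)
  expect_identical(none$excluded_count, length(excl))
  # the same substituent from several donors is counted once
  rep_donors <- donors[rep(1, 5), ]
  rep_donors$id <- paste0("r", 1:5)
  lib1 <- build_fragment_library(rep_donors)
  lib2 <- build_fragment_library(donors[1, ])
  expect_identical(lib1$fragments, lib2$fragments)
})

test_that("invalid donors are skipped with a warning; empty set warns", {
  d <- tibble::tibble(id = c("ok", "bad"), smiles = c("CC(=O)Nc1ccccc1", "C1CC"))
  expect_warning(lib <- build_fragment_library(d), "bad")
  expect_identical(lib$source_count, 1L)
  expect_warning(build_fragment_library(tibble::tibble(id = character(),
                                                       smiles = character())),
                 "Empty donor")
})

test_that("enumeration attaches every novel valid fragment exactly once", {
  core <- "*Nc1ccc(-c2ccc(F)cc2)cc1"
  frags <- c("*C(=O)C", "*C(=O)CC", "*C(=O)CCC", "*C(=O)c1ccccc1")
  v <- enumerate_virtual(core, frags)
  expect_identical(nrow(v$compounds), 4L)
  expect_identical(v$n_invalid + v$n_duplicate + v$n_existing +
                     nrow(v$compounds), v$n_fragments)
  # brute-force oracle: attach, canonicalize, set-filter independently
  oracle <- canonical_smiles(paste0(
    "O=C(", c("C", "CC", "CCC", "c1ccccc1"), ")Nc1ccc(-c2ccc(F)cc2)cc1"))
  expect_setequal(v$compounds$smiles, oracle)
})

test_that("products identical to assayed members are filtered out", {
  core <- "*Nc1ccc(-c2ccc(F)cc2)cc1"
  frags <- c("*C(=O)C", "*C(=O)CC")
  existing <- canonical_smiles("CC(=O)Nc1ccc(-c2ccc(F)cc2)cc1")
  v <- enumerate_virtual(core, frags, existing = existing)
  expect_identical(nrow(v$compounds), 1L)
  expect_identical(v$n_existing, 1L)
  expect_false(existing %in% v$compounds$smiles)
})

test_that("virtual compounds decompose back to the core (round trip)", {
  core <- "*Nc1ccc(Oc2ccc(Cl)cc2)cc1"
  frags <- c("*C(=O)CCC", "*C(=O)COC", "*C(=O)c1ccc(F)cc1")
  v <- enumerate_virtual(core, frags)
  cuts <- recap_single_cut(v$compounds[, c("id", "smiles")])
  core_can <- canonical_smiles(core)
  expect_true(all(vapply(split(cuts$core, cuts$id),
                         function(cs) core_can %in% cs, TRUE)))
})

test_that("enumeration is idempotent on its own fragment set", {
  core <- "*Nc1ccc(-c2ccc(C)cc2)cc1"
  frags <- c("*C(=O)C", "*C(=O)CCCC", "*C(=O)C1CCCC1")
  v1 <- enumerate_virtual(core, frags)
  v2 <- enumerate_virtual(core, v1$compounds$fragment)
  expect_identical(v1$compounds$smiles, v2$compounds$smiles)
})

test_that("a core must have exactly one attachment point", {
  expect_error(enumerate_virtual("CCO", "*C"), "exactly one")
  expect_error(enumerate_virtual("*N(*)C", "*C"), "exactly one")
})

test_that("virtual ids are deterministic content hashes", {
  core <- "*Nc1ccc(-c2ccc(F)cc2)cc1"
  v1 <- enumerate_virtual(core, "*C(=O)CC")
  v2 <- enumerate_virtual(core, "*C(=O)CC")
  expect_identical(v1$compounds$id, v2$compounds$id)
  expect_match(v1$compounds$id, "^v_[0-9a-f]{8}$")
})
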