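test_that("ligand efficiency follows LE = 1.37 * pIC50 / N", {
  expect_equal(ligand_efficiency(1e-5, 20), 1.37 * 5 / 20)  # 0.3425
  expect_equal(ligand_efficiency(1, 12), 0)
  expect_equal(ligand_efficiency(1e-6, 40),
               ligand_efficiency(1e-6, 20) / 2)
  expect_error(ligand_efficiency(0, 10), "positive")
  expect_error(ligand_efficiency(1e-6, 0), "at least 1")
})

test_that("lead selection maximizes LE with deterministic tie-breaks", {
  m <- tibble::tibble(id = c("a", "b"),
                      active = TRUE,
                      potency = c(1e-6, 1e-5),
                      n_heavy = c(30L, 20L))
  expect_identical(select_lead(m), "b")  # LE 0.3425 beats 0.274

  # exact LE tie: 1.37*6/30 == 1.37*4/20 -> higher potency wins
  tie <- tibble::tibble(id = c("lo", "hi"), active = TRUE,
                        potency = c(1e-4, 1e-6), n_heavy = c(20L, 30L))
  expect_identical(select_lead(tie), "hi")
  # full tie on LE and potency: smaller molecule, then id
  tie2 <- tibble::tibble(id = c("z", "a"), active = TRUE,
                         potency = 1e-6, n_heavy = 25L)
  expect_identical(select_lead(tie2), "a")
  expect_error(select_lead(tibble::tibble(id = "x", active = FALSE,
                                          potency = 1e-6, n_heavy = 10L)),
               "No active")
})

test_that("lead selection agrees with a brute-force LE maximum", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    m <- tibble::tibble(id = sprintf("c%02d", sample(n)),
                        active = runif(n) < 0.7,
                        potency = 10^-runif(n, 4, 9),
                        n_heavy = sample(10:45, n, replace = TRUE))
    if (!any(m$active)) m$active[1] <- TRUE
    lead <- select_lead(m)
    cand <- m[m$active, ]
    le <- 1.37 * (-log10(cand$potency)) / cand$n_heavy
    expect_true(lead %in% cand$id[abs(le - max(le)) < 1e-15])
  }
})

test_that("compounds sharing a core are grouped into one series", {
  comp <- tibble::tibble(
    id = c("m1", "m2", "m3", "lone"),
    smiles = c("CC(=O)Nc1ccc(F)cc1", "CCC(=O)Nc1ccc(F)cc1",
               "CCCC(=O)Nc1ccc(F)cc1", "CCOCC"),
    assay_id = "A1",
    active = c(TRUE, FALSE, FALSE, FALSE),
    potency = c(1e-6, NA, NA, NA))
  ser <- suppressWarnings(
    extract_series(comp, min_members = 3, min_actives = 1))
  expect_identical(nrow(ser), 1L)
  expect_identical(ser$n_members, 3L)
  expect_identical(ser$lead_id, "m1")
  expect_identical(ser$core, canonical_smiles("*Nc1ccc(F)cc1"))
  # brute-force oracle: group every (core, id) pair and filter
  cuts <- recap_single_cut(comp[1:3, c("id", "smiles")])
  grp <- table(cuts$core)
  expect_identical(unname(grp[ser$core]), 3L)
  # every member decomposes as core + its own substituent
  mem <- ser$members[[1]]
  expect_identical(reattach_fragments(ser$core, mem$substituent), mem$smiles)
})

test_that("qualification filters enforce member and active minimums", {
  alpha <- progsat:::substituent_alphabet()
  r <- alpha$r_group[seq_len(35)]
  comp <- tibble::tibble(
    id = sprintf("c%02d", 1:35),
    smiles = paste0("O=C(", r, ")Nc1ccc(-c2ccc(F)cc2)cc1"),
    assay_id = "A9",
    active = c(TRUE, TRUE, rep(FALSE, 33)),
    potency = c(1e-6, 1e-7, rep(NA, 33)))
  # 35 members but only 2 actives: excluded under defaults
  expect_error(suppressWarnings(score_saturation(comp, donors = "CCO")),
               "No qualifying")
  expect_identical(nrow(extract_series(comp)), 0L)
  comp$active[3] <- TRUE; comp$potency[3] <- 1e-6
  ser <- extract_series(comp)
  expect_identical(nrow(ser), 1L)
  expect_gte(ser$n_members, 30L)
  expect_gte(ser$n_actives, 3L)
})

test_that("series extraction is invariant to compound order", {
  mols <- fixture_molecules(40, seed = 9)
  comp <- tibble::tibble(id = mols$id, smiles = mols$smiles,
                         assay_id = "A1",
                         active = rep(c(TRUE, FALSE), 20),
                         potency = ifelse(rep(c(TRUE, FALSE), 20), 1e-6, NA))
  a <- suppressWarnings(extract_series(comp, min_members = 2, min_actives = 1))
  perm <- comp[rev(seq_len(nrow(comp))), ]
  b <- suppressWarnings(extract_series(perm, min_members = 2, min_actives = 1))
  expect_identical(a, b)
})

test_that("duplicate ids are rejected", {
  comp <- tibble::tibble(id = c("x", "x"), smiles = c("CCO", "CCC"),
                         assay_id = "A", active = TRUE, potency = 1e-6)
  expect_error(extract_series(comp), "Duplicate")
})
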