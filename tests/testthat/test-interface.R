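cli_path <- function() {
  p <- system.file("cli", "progsat.R", package = "progsat")
  if (nzchar(p)) p else file.path("..", "..", "inst", "cli", "progsat.R")
}

run_cli <- function(args) {
  out <- suppressWarnings(
    system2(file.path(R.home("bin"), "Rscript"), c(cli_path(), args),
            stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SMILES reader reports the offending line of malformed input", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "", "c1ccccc1 mol2", "C1CC broken"), f)
  expect_error(read_smiles(f), "line 4")
  writeLines(c("CCO mol1", "CC"), f)
  ok <- read_smiles(f)
  expect_identical(ok$id, c("mol1", "mol2"))
})

test_that("SDF reader returns canonical structures with titles", {
  f <- withr::local_tempfile(fileext = ".sdf")
  sdf <- ChemmineR::smiles2sdf(c(ben = "c1ccccc1", eth = "CCO"))
  ChemmineR::write.SDF(sdf, f)
  got <- read_sdf(f)
  expect_identical(got$smiles, canonical_smiles(c("c1ccccc1", "CCO")))
})

test_that("activity tables are validated column by column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,assay_id,active,potency_M",
               "c1,A,1,1e-6", "c2,A,0,"), f)
  act <- read_activity(f)
  expect_identical(act$active, c(TRUE, FALSE))
  expect_equal(act$potency, c(1e-6, NA))
  writeLines(c("id,assay_id", "c1,A"), f)
  expect_error(read_activity(f), "active")
})

test_that("score reports convert losslessly between JSON and CSV", {
  ex <- worked_example()
  res <- score_saturation(ex$compounds, donors = ex$donors,
                          min_members = 6, min_actives = 3)
  dir <- withr::local_tempdir()
  paths <- write_saturation_report(res, dir)
  from_json <- read_saturation_report(paths[["json"]])
  from_csv <- read_saturation_report(paths[["csv"]])
  num <- names(from_json)[vapply(from_json, is.double, TRUE)]
  for (j in num) {
    expect_equal(signif(from_json[[j]], 12), from_csv[[j]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_identical(from_json$series_id, from_csv$series_id)
  expect_identical(from_json$category, from_csv$category)
  # every reported number is recomputable from the result object
  expect_equal(from_json$raw_global, res$scores$raw_global)
})

test_that("series manifests round-trip and rescoring them is deterministic", {
  ex <- worked_example()
  ser <- extract_series(ex$compounds, min_members = 6, min_actives = 3)
  dir <- withr::local_tempdir()
  write_series_files(ser, dir)
  back <- read_series_manifest(file.path(dir, "series_manifest.json"))
  expect_identical(back$series_id, ser$series_id)
  expect_identical(back$lead_id, ser$lead_id)
  expect_equal(back$members[[1]], ser$members[[1]])
  r1 <- score_saturation(series = ser, donors = ex$donors)
  r2 <- score_saturation(series = back, donors = ex$donors)
  expect_equal(r1$scores, r2$scores)
})

test_that("the CLI scores a generated fixture set end to end", {
  dir <- withr::local_tempdir()
  fx <- file.path(dir, "fx"); out <- file.path(dir, "res")
  r1 <- run_cli(c("fixtures", "--seed", "7", "--out", fx,
                  "--n-members", "8", "--n-actives", "3"))
  expect_identical(r1$status, 0L)
  expect_true(file.exists(file.path(fx, "activity.csv")))
  r2 <- run_cli(c("score", "--compounds", file.path(fx, "compounds.smi"),
                  "--activity", file.path(fx, "activity.csv"),
                  "--donors", file.path(fx, "donors.smi"),
                  "--out", out, "--min-members", "8", "--min-actives", "3"))
  expect_identical(r2$status, 0L)
  rep <- jsonlite::read_json(file.path(out, "saturation_report.json"),
                             simplifyVector = TRUE)
  expect_identical(nrow(rep$scores), 4L)
  expect_true(all(rep$scores$category %in%
                    c("low/low", "low/high", "high/low", "high/high")))
  expect_true(file.exists(file.path(out, "run_manifest.json")))
  # determinism: a second identical run writes an identical report
  out2 <- file.path(dir, "res2")
  r3 <- run_cli(c("score", "--compounds", file.path(fx, "compounds.smi"),
                  "--activity", file.path(fx, "activity.csv"),
                  "--donors", file.path(fx, "donors.smi"),
                  "--out", out2, "--min-members", "8", "--min-actives", "3"))
  expect_identical(r3$status, 0L)
  expect_identical(readLines(file.path(out, "saturation_report.csv")),
                   readLines(file.path(out2, "saturation_report.csv")))
})

test_that("the CLI exits 2 on malformed input naming the line, 3 on empty series", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.smi")
  writeLines(c("CCO c1", "C1CC c2"), bad)
  act <- file.path(dir, "act.csv")
  writeLines(c("id,assay_id,active,potency_M", "c1,A,1,1e-6", "c2,A,0,"),
             act)
  don <- file.path(dir, "don.smi"); writeLines("CC(=O)Nc1ccccc1 d1", don)
  r <- run_cli(c("score", "--compounds", bad, "--activity", act,
                 "--donors", don, "--out", file.path(dir, "o")))
  expect_identical(r$status, 2L)
  expect_true(any(grepl("line 2", r$output)))

  ok <- file.path(dir, "ok.smi")
  writeLines(c("CC(=O)Nc1ccccc1 c1", "CCC(=O)Nc1ccccc1 c2"), ok)
  r2 <- run_cli(c("score", "--compounds", ok, "--activity", act,
                  "--donors", don, "--out", file.path(dir, "o")))
  expect_identical(r2$status, 3L)

  r3 <- run_cli(c("classify", "--z-global", "1.52", "--z-local", "2.39"))
  expect_identical(r3$status, 0L)
  expect_true(any(grepl("high/high", r3$output)))
})

test_that("a YAML config is honored with command-line override", {
  dir <- withr::local_tempdir()
  ex <- worked_example()
  write_dataset_files(ex, dir)
  cfgf <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(compounds = file.path(dir, "compounds.smi"),
                        activity = file.path(dir, "activity.csv"),
                        donors = file.path(dir, "donors.smi"),
                        out = file.path(dir, "res"),
                        min_members = 6, min_actives = 3), cfgf)
  r <- run_cli(c("score", "--config", cfgf))
  expect_identical(r$status, 0L)
  rep <- read_saturation_report(file.path(dir, "res",
                                          "saturation_report.json"))
  expect_identical(nrow(rep), 2L)
})
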