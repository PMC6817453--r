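# Cohort container, CSV dialect and invariant checking.

test_that("cohort CSV round-trips losslessly, including NA cells", {
  co <- generateCohort(generatorConfig(nPatients = 10, naRate = 0.1, seed = 3))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeCohort(co, f1)
  co2 <- readCohort(f1)
  expect_identical(cohortToDataFrame(co), cohortToDataFrame(co2))
  expect_equal(ncol(co2), ncol(co))
  # write . read . write is byte-identical
  writeCohort(co2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # NA cells appear as the literal token
  expect_true(any(grepl(",NA,", readLines(f1)[-1], fixed = TRUE)))
})

test_that("an averaged cohort (fractional scores) survives the round trip", {
  sc <- matrix(0, 10, 2, dimnames = list(markerPanel(), NULL))
  sc["B7-H3", ] <- c(1, 0)   # blocks disagree -> average 0.5
  sc["CK7", ] <- c(8, 4)
  co <- collapseBlocks(make_cohort(sc, patient_id = c("P1", "P1"),
                                   component = c("in_situ", "in_situ"),
                                   block_id = c("B1", "B2")))
  expect_equal(unname(scores(co)["B7-H3", 1]), 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  writeCohort(co, f)
  co2 <- readCohort(f)
  expect_true(blocksAveraged(co2))
  expect_identical(cohortToDataFrame(co), cohortToDataFrame(co2))
})

test_that("empty cohorts read and write as header-only CSV", {
  m <- matrix(numeric(), 10, 0, dimnames = list(markerPanel(), NULL))
  co <- IHCCohort(m, m, .emptyCovariates())
  f <- withr::local_tempfile(fileext = ".csv")
  writeCohort(co, f)
  expect_length(readLines(f), 1)
  expect_equal(ncol(readCohort(f)), 0)
})

test_that("schema and range violations are hard errors naming the culprit", {
  co <- generateCohort(generatorConfig(nPatients = 3, seed = 1))
  df <- cohortToDataFrame(co)
  expect_error(cohortFromDataFrame(df[, setdiff(colnames(df), "b7h3_pct")]),
               "schema mismatch.*b7h3_pct")
  bad <- df
  bad$b7h3_pct[2] <- 5
  bad <- bad[, !grepl("_score$", colnames(bad))]
  expect_error(cohortFromDataFrame(bad), "percent_category out of range")
  bad2 <- df[, !grepl("_score$", colnames(df))]
  bad2$ck7_int[1] <- 4
  expect_error(cohortFromDataFrame(bad2), "intensity out of range")
})

test_that("validateCohort reports invariant violations without aborting", {
  co <- generateCohort(generatorConfig(nPatients = 5, seed = 2))
  expect_length(validateCohort(co), 0)

  # an unattainable pre-averaging composite (5 has no factorization)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = lapply(SummarizedExperiment::assays(co), identity),
    colData = SummarizedExperiment::colData(co),
    metadata = list(blocks_averaged = FALSE))
  SummarizedExperiment::assay(se, "score")[1, 1] <- 5
  v <- validateCohort(se)
  expect_length(v, 1)
  expect_match(v, "not an attainable")

  # duplicate record tuple
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = lapply(SummarizedExperiment::assays(co),
                    function(a) a[, c(1, 1)]),
    colData = SummarizedExperiment::colData(co)[c(1, 1), ],
    metadata = list(blocks_averaged = FALSE))
  expect_match(validateCohort(se2), "duplicate", all = FALSE)

  # resection b without a
  co3 <- generateCohort(generatorConfig(nPatients = 4,
                                        secondResectionRate = 0, seed = 2))
  se3 <- SummarizedExperiment::SummarizedExperiment(
    assays = lapply(SummarizedExperiment::assays(co3), identity),
    colData = SummarizedExperiment::colData(co3),
    metadata = list(blocks_averaged = FALSE))
  SummarizedExperiment::colData(se3)$resection_label[1] <- "b"
  expect_match(validateCohort(se3), "without 'a'", all = FALSE)

  # negative CD8 density and vocabulary violations
  se4 <- se
  SummarizedExperiment::assay(se4, "score")[1, 1] <- 0
  SummarizedExperiment::assay(se4, "percent")[1, 1] <- 0
  SummarizedExperiment::assay(se4, "intensity")[1, 1] <- 0
  SummarizedExperiment::colData(se4)$cd8_density[1] <- -3
  SummarizedExperiment::colData(se4)$site[2] <- "elbow"
  v4 <- validateCohort(se4)
  expect_match(v4, "cd8_density negative", all = FALSE)
  expect_match(v4, "site 'elbow'", all = FALSE)
})

test_that("the attainable composite set is exactly the 5x4 product table", {
  expect_identical(attainableCompositeScores(),
                   c(0, 1, 2, 3, 4, 6, 8, 9, 12))
})
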