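# Composite scoring, block averaging, positivity calls, summaries.

test_that("compositeScore matches the exhaustive 5x4 product table", {
  grid <- expand.grid(pct = 0:4, int = 0:3)
  expect_equal(compositeScore(grid$pct, grid$int), grid$pct * grid$int)
  expect_equal(max(compositeScore(grid$pct, grid$int)), 12)
  expect_identical(sort(unique(compositeScore(grid$pct, grid$int))),
                   attainableCompositeScores())
  expect_equal(compositeScore(4, 3), 12)
  expect_equal(compositeScore(0, 3), 0)
  expect_equal(compositeScore(2, 3), 6)
  expect_error(compositeScore(5, 1), "percent_category out of range")
  expect_error(compositeScore(1, 4), "intensity out of range")
})

test_that("averageBlocks follows the averaging contract", {
  expect_equal(averageBlocks(c(12, 12)), 12)
  expect_equal(averageBlocks(c(8, 4)), 6)
  for (x in c(0, 0.5, 7)) expect_equal(averageBlocks(x), x)
  expect_true(is.na(averageBlocks(c(NA_real_, NA_real_))))
  expect_error(averageBlocks(c(3, NA)), "mixed")
  expect_error(averageBlocks(numeric()), "no block scores")
})

test_that("collapseBlocks averages duplicate blocks and flags the cohort", {
  sc <- matrix(0, 10, 3, dimnames = list(markerPanel(), NULL))
  sc["B7-H3", ] <- c(12, 8, 6)   # P1 has blocks B1+B2, P2 single
  sc["MAGE-A", ] <- c(NA, NA, 9) # NA shared across both blocks
  co <- make_cohort(sc, patient_id = c("P1", "P1", "P2"),
                    component = "in_situ", block_id = c("B1", "B2", "B1"))
  cc <- collapseBlocks(co)
  expect_equal(ncol(cc), 2)
  expect_true(blocksAveraged(cc))
  expect_equal(unname(scores(cc)["B7-H3", ]), c(10, 6))
  expect_true(is.na(scores(cc)["MAGE-A", 1]))
  expect_length(validateCohort(cc), 0)
  # idempotent
  expect_identical(cohortToDataFrame(collapseBlocks(cc)),
                   cohortToDataFrame(cc))
})

test_that("positivity is strictly greater-than-zero with NA propagation", {
  expect_identical(callPositivity(c(0, 0.5, 12, NA)),
                   c("negative", "positive", "positive", NA))
  expect_error(callPositivity(13), "outside")
})

test_that("summarizeMarker reproduces the worked-example marginals", {
  co <- workedExampleCohort()
  s <- summarizeMarker(co, "B7-H3", "in_situ")
  expect_equal(s$n_scored, 49)
  expect_equal(s$n_positive, 46)
  expect_equal(round(s$pct_positive, 1), 93.9)
})

test_that("mean_score conventions and degenerate summaries behave as declared", {
  sc <- matrix(0, 10, 3, dimnames = list(markerPanel(), NULL))
  sc["B7-H4", ] <- c(12, 6, 0)
  sc["CK7", ] <- 4
  co <- make_cohort(sc, patient_id = c("A", "B", "C"), component = "in_situ")
  expect_equal(summarizeMarker(co, "B7-H4", "in_situ",
                               meanOver = "positive")$mean_score, 9)
  expect_equal(summarizeMarker(co, "B7-H4", "in_situ",
                               meanOver = "scored")$mean_score, 6)
  # all-positive marker
  expect_equal(summarizeMarker(co, "CK7", "in_situ")$pct_positive, 100)
  # all-negative marker has no positive-case mean
  expect_true(is.na(summarizeMarker(co, "B2M", "in_situ")$mean_score))
  expect_error(summarizeMarker(co, "B7-H4", "invasive"), "no scored records")
  expect_error(summarizeMarker(co, "HER2", "in_situ"), "unknown marker")
})

test_that("stratified counts partition the unstratified counts", {
  co <- generateCohort(generatorConfig(nPatients = 40, seed = 6))
  tot <- summarizeMarker(co, "B7-H3", "in_situ")
  parts <- lapply(c("primary", "secondary"), function(l)
    tryCatch(summarizeMarker(co, "B7-H3", "in_situ",
                             stratum = list(origin = l)),
             error = function(e) NULL))
  expect_equal(sum(vapply(parts, function(p) if (is.null(p)) 0L else p$n_scored,
                          integer(1))), tot$n_scored)
})

test_that("summaries are invariant to record order", {
  co <- generateCohort(generatorConfig(nPatients = 20, seed = 9))
  perm <- withr::with_seed(1, sample(ncol(co)))
  co2 <- co[, perm]
  for (m in c("B7-H3", "CK20"))
    expect_equal(summarizeMarker(co2, m, "in_situ"),
                 summarizeMarker(co, m, "in_situ"))
})

test_that("TIL summary counts specimens, not component rows", {
  sc <- matrix(4, 10, 4, dimnames = list(markerPanel(), NULL))
  # two specimens, one with both components (TIL fields shared)
  co <- make_cohort(sc, patient_id = c("P1", "P1", "P2", "P3"),
                    component = c("in_situ", "invasive", "in_situ", "in_situ"),
                    til_b7h3 = c(1, 1, 1, 2), til_pdl2 = c(0, 0, 1, 0))
  s <- summarizeTIL(co)
  expect_equal(s$n_scored, rep(3, 4))
  pdl2 <- s[s$til_marker == "TIL PD-L2", ]
  expect_equal(pdl2$n_positive, 1)
  expect_equal(round(pdl2$pct_positive, 1), 33.3)
  expect_equal(s$median_category[s$til_marker == "TIL B7-H3"], 1)
})

test_that("a 4-of-54 TIL PD-L2 pattern yields 7.4% positive", {
  sc <- matrix(4, 10, 54, dimnames = list(markerPanel(), NULL))
  co <- make_cohort(sc, patient_id = sprintf("P%02d", 1:54),
                    component = "in_situ",
                    til_pdl2 = c(rep(1, 4), rep(0, 50)))
  s <- summarizeTIL(co)
  expect_equal(round(s$pct_positive[s$til_marker == "TIL PD-L2"], 1), 7.4)
})
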