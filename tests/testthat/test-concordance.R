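# Rank/cosine concordance statistics and cohort-level agreement summaries.

test_that("spearmanRho handles monotone, tied and degenerate inputs", {
  expect_equal(spearmanRho(1:5, (1:5)^2), 1)
  expect_equal(spearmanRho(1:5, rev(1:5)), -1)
  expect_equal(spearmanRho(c(1, 2, 2, 4), c(1, 3, 3, 5)), 1)
  expect_true(is.na(spearmanRho(rep(2, 4), 1:4)))     # constant -> undefined
  expect_true(is.na(spearmanRho(c(1, NA), c(2, 3)))) # < 2 complete pairs
})

test_that("cosineSimilarity handles identity, orthogonality and zero vectors", {
  expect_equal(cosineSimilarity(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 2), c(2, 4)), 1)
  expect_true(is.na(cosineSimilarity(c(0, 0), c(1, 2))))
})

test_that("kendallTauB matches the tie-corrected pair-count definition", {
  expect_equal(kendallTauB(1:4, 1:4), 1)
  expect_equal(kendallTauB(c(1, 2, 3), c(3, 2, 1)), -1)
  x <- c(1, 1, 2, 3); y <- c(1, 2, 2, 3)
  expect_equal(kendallTauB(x, y), oracle_tau_b(x, y))
  expect_true(is.na(kendallTauB(rep(1, 3), 1:3)))
})

test_that("rank statistics agree with brute-force oracles on a random sweep", {
  cases <- withr::with_seed(17, replicate(300, {
    n <- sample(2:8, 1)
    list(x = sample(0:3, n, replace = TRUE), y = sample(0:3, n, replace = TRUE))
  }, simplify = FALSE))
  for (cs in cases) {
    expect_equal(kendallTauB(cs$x, cs$y), oracle_tau_b(cs$x, cs$y),
                 tolerance = 1e-12)
    expect_equal(spearmanRho(cs$x, cs$y), oracle_spearman(cs$x, cs$y),
                 tolerance = 1e-12)
  }
})

test_that("all three measures are invariant to positive rescaling", {
  x <- c(0, 4, 8, 12, 6); y <- c(1, 3, 9, 12, 2)
  expect_equal(spearmanRho(2.5 * x, y), spearmanRho(x, y))
  expect_equal(kendallTauB(x, 10 * y), kendallTauB(x, y))
  expect_equal(cosineSimilarity(3 * x, 0.5 * y), cosineSimilarity(x, y))
})

test_that("pairwise deletion: an incomplete pair never changes the result", {
  x <- c(2, 5, 7, 1); y <- c(3, 6, 2, 8)
  for (f in list(spearmanRho, cosineSimilarity, kendallTauB)) {
    expect_equal(f(c(x, NA), c(y, 4)), f(x, y))
    expect_equal(f(c(x, 9), c(y, NA)), f(x, y))
  }
})

test_that("componentConcordance: identical components give perfect agreement", {
  sc <- matrix(c(0, 12, 4, 6, 0, 9, 8, 2, 12, 1), 10, 4,
               dimnames = list(markerPanel(), NULL))
  co <- make_paired_cohort(sc, sc)
  cc <- componentConcordance(co)
  expect_equal(cc$case$value, rep(1, 4))
  expect_equal(cc$case$n_used, rep(10, 4))
  defined <- !cc$marker$undefined
  expect_equal(cc$marker$value[defined],
               rep(1, sum(defined)))
})

test_that("componentConcordance is near zero for independent components", {
  cfg <- generatorConfig(
    nPatients = 400, componentConcordance = 0, naRate = 0,
    secondResectionRate = 0, dualBlockRate = 0, bothComponentRate = 1,
    covariateFreqs = list(extent = c(invasive = 1)))
  co <- generateCohort(cfg, seed = 4)
  cc <- componentConcordance(co)
  v <- cc$case$value[!cc$case$undefined]
  expect_lt(abs(mean(v)), 3 * stats::sd(v) / sqrt(length(v)) + 0.02)
})

test_that("resectionConcordance pairs resections and skips single-resection patients", {
  sc <- matrix(c(0, 12, 4, 6, 0, 9, 8, 2, 12, 1), 10, 5,
               dimnames = list(markerPanel(), NULL))
  co <- make_cohort(sc, patient_id = c("P1", "P1", "P2", "P2", "P3"),
                    resection_label = c("a", "b", "a", "b", "none"),
                    component = "in_situ")
  rc <- resectionConcordance(co)
  expect_equal(sort(rc$case$id), c("P1", "P2"))
  expect_equal(rc$case$value, rep(1, 2))
})

test_that("per-marker resection similarity decreases with drift noise", {
  base <- withr::with_seed(5, matrix(sample(attainableCompositeScores(),
                                            10 * 30, replace = TRUE),
                                     10, 30, dimnames = list(markerPanel(), NULL)))
  snap <- function(m) {
    att <- attainableCompositeScores()
    matrix(att[apply(abs(outer(c(m), att, "-")), 1, which.min)],
           nrow(m), ncol(m), dimnames = dimnames(m))
  }
  drift <- function(noise) {
    b <- snap(withr::with_seed(6, pmin(pmax(base + matrix(
      sample(seq(-noise, noise), 10 * 30, replace = TRUE), 10, 30), 0), 12)))
    co <- make_cohort(cbind(base, b),
                      patient_id = rep(sprintf("P%02d", 1:30), 2),
                      resection_label = rep(c("a", "b"), each = 30),
                      component = "in_situ")
    mean(resectionConcordance(co)$marker$value, na.rm = TRUE)
  }
  expect_gt(drift(1), drift(6))
  expect_gt(drift(6), drift(12))
})

test_that("covariate correlations binarize vital status and flag undefined", {
  sc <- matrix(0, 10, 6, dimnames = list(markerPanel(), NULL))
  sc["B7-H3", ] <- c(1, 2, 3, 4, 6, 8)
  co <- make_cohort(sc, patient_id = sprintf("P%d", 1:6),
                    component = "in_situ",
                    cd8_density = c(10, 20, 30, 40, 50, 60),
                    vital_status = c("alive", "alive", "death_from_disease",
                                     "death_unrelated", "unknown", "alive"))
  cv <- covariateCorrelations(co, "in_situ")
  cd8row <- cv[cv$var_a == "cd8_density" & cv$var_b == "B7-H3", ]
  expect_equal(cd8row$value, 1)
  vit <- cv[cv$var_a == "vital_status" & cv$var_b == "B7-H3", ]
  expect_equal(vit$n_used, 5)   # unknown removed
  expect_equal(vit$value, oracle_tau_b(c(1, 1, 0, 0, 1), c(1, 2, 3, 4, 8)))
  # constant marker -> undefined, never silently zero
  pd <- cv[cv$var_a == "cd8_density" & cv$var_b == "PD-L2", ]
  expect_true(pd$undefined)
  expect_true(is.na(pd$value))
})
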