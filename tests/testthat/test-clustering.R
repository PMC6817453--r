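# Manhattan-with-NA distances and complete-linkage clustering.

test_that("manhattanDistanceNA applies the exclude-and-rescale convention", {
  expect_equal(manhattanDistanceNA(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(manhattanDistanceNA(c(0, 12), c(12, 0)), 24)
  expect_equal(manhattanDistanceNA(c(1, NA, 3, 5), c(2, 7, NA, 5)), 2)
  expect_error(manhattanDistanceNA(c(NA, 1), c(2, NA)), "no complete")
  expect_error(manhattanDistanceNA(1:3, 1:4), "length mismatch")
})

test_that("the distance matches stats::dist with and without missing values", {
  m <- withr::with_seed(21, matrix(sample(c(0:12, NA), 8 * 6, replace = TRUE,
                                          prob = c(rep(1, 13), 3)), 8, 6))
  ours <- matrix(0, 8, 8)
  for (i in 1:7) for (j in (i + 1):8)
    ours[i, j] <- ours[j, i] <-
      tryCatch(manhattanDistanceNA(m[i, ], m[j, ]), error = function(e) NA)
  ref <- as.matrix(stats::dist(m, method = "manhattan"))
  expect_equal(unname(ours), unname(ref))
})

test_that("complete linkage solves small instances exactly", {
  D <- as.matrix(stats::dist(c(0, 1, 10), method = "manhattan"))
  dimnames(D) <- list(c("a", "b", "c"), c("a", "b", "c"))
  den <- completeLinkage(D)
  expect_equal(den@height, c(1, 10))
  expect_equal(sort(den@merge[1, ]), c(-2, -1))   # {0,1} merge first
  # identical items merge first at height 0
  D2 <- as.matrix(stats::dist(c(5, 0, 5), method = "manhattan"))
  den2 <- completeLinkage(D2)
  expect_equal(den2@height[1], 0)
  expect_equal(sort(den2@merge[1, ]), c(-3, -1))
  expect_error(completeLinkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("merge heights agree with the brute-force oracle and hclust (n <= 6)", {
  for (rep in 1:25) {
    n <- withr::with_seed(100 + rep, sample(3:6, 1))
    pts <- withr::with_seed(200 + rep, matrix(sample(0:12, n * 4, replace = TRUE), n))
    D <- as.matrix(stats::dist(pts, method = "manhattan"))
    den <- completeLinkage(D)
    expect_equal(den@height, oracle_complete_heights(D))
    # tie-free instances have a unique complete-linkage tree; with ties
    # hclust may legally pick a different (equally valid) merge order
    if (!any(duplicated(D[upper.tri(D)]))) {
      hc <- stats::hclust(stats::as.dist(D), method = "complete")
      expect_equal(sort(den@height), sort(hc$height))
    }
    expect_false(is.unsorted(den@height))      # no inversions
  }
})

test_that("dendrograms convert to hclust and cut into partitions", {
  pts <- c(0, 1, 2, 20, 21, 22)
  D <- as.matrix(stats::dist(pts, method = "manhattan"))
  dimnames(D) <- list(letters[1:6], letters[1:6])
  den <- completeLinkage(D)
  hc <- as.hclust(den)
  expect_s3_class(hc, "hclust")
  grp <- stats::cutree(hc, k = 2)
  expect_equal(unname(grp), c(1, 1, 1, 2, 2, 2))
})

test_that("clustering is invariant to input order up to the tie rule", {
  m <- withr::with_seed(31, matrix(sample(attainableCompositeScores(),
                                          10 * 14, replace = TRUE), 10, 14,
                                   dimnames = list(markerPanel(), NULL)))
  co <- make_cohort(m, patient_id = sprintf("P%02d", 1:14), component = "in_situ")
  cl1 <- clusterCohort(co, "in_situ")
  perm <- withr::with_seed(32, sample(14))
  cl2 <- clusterCohort(co[, perm], "in_situ")
  expect_equal(sort(cl1@caseDendrogram@height), sort(cl2@caseDendrogram@height))
  part <- function(cl) {
    g <- stats::cutree(as.hclust(cl@caseDendrogram), k = 3)
    unname(split(names(g), g))
  }
  expect_setequal(lapply(part(cl1), sort), lapply(part(cl2), sort))
})

test_that("identical cases sit adjacent and planted partitions are recovered", {
  sig1 <- c(12, 12, 12, 12, 12, 0, 0, 0, 0, 0)
  sig2 <- rev(sig1)
  jit <- withr::with_seed(41, matrix(sample(c(0, 3, 4), 10 * 20, replace = TRUE),
                                     10, 20))
  sc <- cbind(matrix(sig1, 10, 10), matrix(sig2, 10, 10))
  sc <- abs(sc - jit)   # small perturbation toward the interior
  rownames(sc) <- markerPanel()
  co <- make_cohort(sc, patient_id = sprintf("P%02d", 1:20), component = "in_situ")
  cl <- clusterCohort(co, "in_situ")
  grp <- stats::cutree(as.hclust(cl@caseDendrogram), k = 2)
  planted <- rep(1:2, each = 10)
  agree <- max(mean(grp == planted), mean(grp == 3 - planted))
  expect_equal(agree, 1)
  # two byte-identical cases merge first and end up adjacent
  sc2 <- sc; sc2[, 2] <- sc2[, 1]
  co2 <- make_cohort(sc2, patient_id = sprintf("P%02d", 1:20), component = "in_situ")
  cl2 <- clusterCohort(co2, "in_situ")
  ord <- cl2@caseDendrogram@order
  expect_equal(abs(diff(match(c(1, 2), ord))), 1)
})

test_that("fully missing cases are dropped with a warning before clustering", {
  m <- withr::with_seed(51, matrix(sample(attainableCompositeScores(),
                                          10 * 5, replace = TRUE), 10, 5,
                                   dimnames = list(markerPanel(), NULL)))
  m[, 3] <- NA
  co <- make_cohort(m, patient_id = sprintf("P%d", 1:5), component = "in_situ")
  expect_warning(cl <- clusterCohort(co, "in_situ"), "fully missing")
  expect_equal(ncol(cl@matrix), 4)
  expect_false("P3" %in% cl@caseDendrogram@labels)
})
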