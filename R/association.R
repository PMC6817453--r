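# Permutation inference for group differences in percent positive, with
# eligibility filtering, Benjamini-Hochberg FDR control and Fisher exact
# tests for binary TIL markers.

#' Eligibility of a two-group comparison
#'
#' A comparison is tested only when each group has at least
#' `minPerGroup` scored cases and the groups together have at least
#' `minTotal`.
#'
#' @param nA,nB Scored case counts in the two groups.
#' @param minPerGroup Minimum per group (default 3).
#' @param minTotal Minimum total across groups (default 10).
#' @return Logical.
#' @export
#' @examples
#' eligibility(3, 7)   # TRUE
#' eligibility(2, 100) # FALSE
eligibility <- function(nA, nB, minPerGroup = 3, minTotal = 10) {
  nA >= minPerGroup & nB >= minPerGroup & (nA + nB) >= minTotal
}

#' Absolute difference in percent positive between two groups
#'
#' The test statistic of the permutation screen:
#' `|100 * mean(a) - 100 * mean(b)|` on positivity flags.
#'
#' @param groupA,groupB Logical/0-1 positivity flags, both nonempty.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' percentPositiveStat(c(1, 1, 0), c(1, 0, 0, 0))  # 41.67
percentPositiveStat <- function(groupA, groupB) {
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("empty group", call. = FALSE)
  abs(100 * mean(groupA) - 100 * mean(groupB))
}

#' Permutation test for a difference in percent positive
#'
#' Pools the positivity flags of the two groups and reshuffles the group
#' assignment (preserving group sizes) `nIter` times; the p-value is
#' `(1 + #{permuted stat >= observed}) / (nIter + 1)` (add-one smoothing, so
#' p is never below `1/(nIter+1)` and never exactly 0). Flags are sorted
#' within each group before pooling, so the result is invariant to
#' within-group record order given the same seed.
#'
#' @param groupA,groupB Logical/0-1 positivity flags.
#' @param nIter Number of random shuffles (default 1000).
#' @param seed Optional integer seed; the caller's RNG stream is restored.
#' @return p-value in `(0, 1]`.
#' @export
#' @examples
#' permutationTest(rep(1, 5), rep(0, 5), nIter = 500, seed = 1)
permutationTest <- function(groupA, groupB, nIter = 1000, seed = NULL) {
  a <- sort(as.numeric(groupA)); b <- sort(as.numeric(groupB))
  obs <- percentPositiveStat(a, b)
  pool <- c(a, b)
  n <- length(pool); nA <- length(a)
  .withSeed(seed, {
    hits <- 0L
    for (i in seq_len(nIter)) {
      idx <- sample.int(n, nA)
      s <- abs(100 * mean(pool[idx]) - 100 * mean(pool[-idx]))
      if (s >= obs - 1e-9) hits <- hits + 1L
    }
    (1 + hits) / (nIter + 1)
  })
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pValues Numeric vector of p-values in `(0, 1]`.
#' @param fdr Target false discovery rate (default 0.05).
#' @return List with `adjusted` (BH-adjusted p-values) and `reject`
#'   (`adjusted <= fdr`); both empty for empty input.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))$adjusted  # 0.03 0.03 0.03
bhAdjust <- function(pValues, fdr = 0.05) {
  if (length(pValues) == 0)
    return(list(adjusted = numeric(), reject = logical()))
  if (any(pValues <= 0 | pValues > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pValues, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= fdr)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities (margins
#' fixed) of all tables at most as probable as the observed one. A table
#' with a zero margin admits a single configuration and returns 1.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @return p-value in `(0, 1]`.
#' @export
#' @examples
#' fisherExact2x2(matrix(c(2, 0, 0, 2), 2))  # 1/3
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0)) stop("negative count", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Permutation screen of marker positivity across covariate contrasts
#'
#' For every (contrast, marker) pair in one tumor component: counts scored
#' cases per group, checks [eligibility()], computes the observed
#' [percentPositiveStat()] and its [permutationTest()] p-value, and applies
#' [bhAdjust()] across markers *within* each covariate contrast (that is the
#' multiple-testing family). Ineligible comparisons are flagged and carried
#' with `NA` p-values, never dropped.
#'
#' @param cohort An [IHCCohort].
#' @param contrasts `data.frame` with columns `covariate`, `level_a`,
#'   `level_b` (pairwise contrasts; multi-level covariates are screened as
#'   declared pairs, not omnibus tests).
#' @param component Tumor component to screen.
#' @param markers Markers to screen (default: full panel).
#' @param nIter Shuffles per test (default 1000).
#' @param seed Root seed; one sub-seed per (contrast, marker) test is drawn
#'   from it, so results do not depend on evaluation order.
#' @param fdr FDR threshold for the reject flag (default 0.05).
#' @param minPerGroup,minTotal Eligibility thresholds.
#' @return `data.frame` of association results: marker, component,
#'   covariate, level_a/b, n_a/b, pct_a/b, stat, p_perm, p_adj, reject,
#'   eligible, n_iter, seed.
#' @export
runAssociationScreen <- function(cohort, contrasts, component,
                                 markers = markerPanel(),
                                 nIter = 1000, seed = 1L, fdr = 0.05,
                                 minPerGroup = 3, minTotal = 10) {
  stopifnot(all(c("covariate", "level_a", "level_b") %in% colnames(contrasts)))
  cohort <- collapseBlocks(cohort)
  sel <- .selectComponent(cohort, component)
  cd <- SummarizedExperiment::colData(cohort)[sel, , drop = FALSE]
  sco <- scores(cohort)[, sel, drop = FALSE]
  nTest <- nrow(contrasts) * length(markers)
  testSeeds <- .withSeed(seed, sample.int(.Machine$integer.max, nTest))

  rows <- list(); t <- 0L
  for (ci in seq_len(nrow(contrasts))) {
    cov <- as.character(contrasts$covariate[ci])
    la <- as.character(contrasts$level_a[ci])
    lb <- as.character(contrasts$level_b[ci])
    g <- as.character(cd[[cov]])
    for (m in markers) {
      t <- t + 1L
      v <- sco[m, ]
      fa <- v[!is.na(v) & !is.na(g) & g == la] > 0
      fb <- v[!is.na(v) & !is.na(g) & g == lb] > 0
      nA <- length(fa); nB <- length(fb)
      elig <- eligibility(nA, nB, minPerGroup, minTotal)
      stat <- if (nA > 0 && nB > 0) percentPositiveStat(fa, fb) else NA_real_
      pPerm <- if (elig) permutationTest(fa, fb, nIter, testSeeds[t]) else NA_real_
      rows[[t]] <- data.frame(
        marker = m, component = component, covariate = cov,
        level_a = la, level_b = lb, n_a = nA, n_b = nB,
        pct_a = if (nA > 0) 100 * mean(fa) else NA_real_,
        pct_b = if (nB > 0) 100 * mean(fb) else NA_real_,
        stat = stat, p_perm = pPerm, p_adj = NA_real_, reject = NA,
        eligible = elig, n_iter = nIter, seed = seed,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  # BH family: all markers within one covariate contrast
  fam <- paste(out$covariate, out$level_a, out$level_b, sep = "|")
  for (f in unique(fam)) {
    idx <- which(fam == f & out$eligible)
    if (length(idx)) {
      adj <- bhAdjust(out$p_perm[idx], fdr)
      out$p_adj[idx] <- adj$adjusted
      out$reject[idx] <- adj$reject
    }
  }
  rownames(out) <- NULL
  out
}
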