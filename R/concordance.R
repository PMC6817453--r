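# Agreement statistics: Spearman (cases), cosine (markers), Kendall tau-b
# (covariate correlations). Missing values are handled by pairwise-complete
# deletion; undefined results (constant or zero vectors) are explicit NA,
# never silently 0.

.completePairs <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

#' Spearman rank correlation with pairwise deletion
#'
#' Pearson correlation of average-tie ranks after pairwise-complete
#' deletion. Undefined (fewer than 2 complete pairs, or a constant vector)
#' returns `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
spearmanRho <- function(x, y) {
  p <- .completePairs(x, y)
  if (p$n < 2) return(NA_real_)
  if (length(unique(p$x)) < 2 || length(unique(p$y)) < 2) return(NA_real_)
  stats::cor(p$x, p$y, method = "spearman")
}

#' Cosine similarity with pairwise deletion
#'
#' `dot(x, y) / (||x|| ||y||)` over pairwise-complete coordinates; a zero
#' vector makes the result undefined (`NA`). On nonnegative composite
#' scores the value lies in \[0, 1\].
#'
#' @param x,y Numeric vectors of equal length.
#' @return Cosine similarity, or `NA` if undefined.
#' @export
cosineSimilarity <- function(x, y) {
  p <- .completePairs(x, y)
  if (p$n < 1) return(NA_real_)
  nx <- sqrt(sum(p$x^2)); ny <- sqrt(sum(p$y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(p$x * p$y) / (nx * ny)
}

#' Kendall tau-b rank correlation with pairwise deletion
#'
#' `(C - D) / sqrt((n0 - n1)(n0 - n2))` with `n0 = n(n-1)/2`, `n1`/`n2` the
#' tie-pair counts in each variable and `C`/`D` the concordant/discordant
#' pair counts. Undefined (constant vector, < 2 complete pairs) returns
#' `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return tau-b in \[-1, 1\], or `NA` if undefined.
#' @export
kendallTauB <- function(x, y) {
  p <- .completePairs(x, y)
  if (p$n < 2) return(NA_real_)
  if (length(unique(p$x)) < 2 || length(unique(p$y)) < 2) return(NA_real_)
  stats::cor(p$x, p$y, method = "kendall")
}

.concordanceRow <- function(unit, id, method, value, nUsed) {
  data.frame(unit = unit, id = id, method = method,
             value = value, n_used = nUsed,
             undefined = is.na(value), stringsAsFactors = FALSE)
}

# pair columns of a collapsed cohort by a key; returns list of (idA, idB)
.pairColumns <- function(cd, keyA, keyB, id) {
  ia <- match(id, keyA); ib <- match(id, keyB)
  keep <- !is.na(ia) & !is.na(ib)
  list(id = id[keep], a = ia[keep], b = ib[keep])
}

#' Concordance between in situ and invasive components of the same case
#'
#' For every case (patient x resection) carrying both components:
#' \itemize{
#'   \item per case, the Spearman correlation between the two 10-marker
#'     composite-score vectors (TIL and CD8 fields never enter);
#'   \item per marker, the cosine similarity between the across-case score
#'     profiles of the two components.
#' }
#'
#' @param cohort An [IHCCohort]; duplicate blocks are averaged first.
#' @return List of two `data.frame`s, `case` and `marker`, each with
#'   columns unit, id, method, value, n_used, undefined.
#' @export
componentConcordance <- function(cohort) {
  cohort <- collapseBlocks(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  sco <- scores(cohort)
  case <- paste(cd$patient_id, cd$resection_label, sep = "|")
  keyIS <- ifelse(cd$component == "in_situ", case, NA)
  keyIV <- ifelse(cd$component == "invasive", case, NA)
  pr <- .pairColumns(cd, keyIS, keyIV, unique(case))
  if (length(pr$id) == 0)
    stop("no case carries both in situ and invasive components", call. = FALSE)
  caseLabel <- sub("\\|", "", sub("\\|none$", "", pr$id))

  caseDf <- do.call(rbind, lapply(seq_along(pr$id), function(k) {
    x <- sco[, pr$a[k]]; y <- sco[, pr$b[k]]
    n <- sum(!is.na(x) & !is.na(y))
    .concordanceRow("case_pair", caseLabel[k], "spearman",
                    spearmanRho(x, y), n)
  }))
  markerDf <- do.call(rbind, lapply(rownames(sco), function(m) {
    x <- sco[m, pr$a]; y <- sco[m, pr$b]
    n <- sum(!is.na(x) & !is.na(y))
    .concordanceRow("marker", m, "cosine", cosineSimilarity(x, y), n)
  }))
  list(case = caseDf, marker = markerDf)
}

#' Concordance between two resections of the same patient
#'
#' For every patient with resections `a` (earliest) and `b`: pairs the
#' records of the component present in both resections (in situ preferred,
#' then invasive, then metastatic) and reports the per-patient Spearman
#' correlation over the 10 markers plus the per-marker cosine similarity
#' across patients. Patients with a single resection are excluded.
#'
#' @param cohort An [IHCCohort]; duplicate blocks are averaged first.
#' @return List of `data.frame`s `case` (per patient) and `marker`.
#' @export
resectionConcordance <- function(cohort) {
  cohort <- collapseBlocks(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  sco <- scores(cohort)
  pats <- unique(cd$patient_id[cd$resection_label == "b"])
  pairA <- integer(); pairB <- integer(); ids <- character()
  for (p in pats) {
    for (comp in .COMPONENTS) {
      ia <- which(cd$patient_id == p & cd$resection_label == "a" &
                    cd$component == comp)
      ib <- which(cd$patient_id == p & cd$resection_label == "b" &
                    cd$component == comp)
      if (length(ia) == 1 && length(ib) == 1) {
        pairA <- c(pairA, ia); pairB <- c(pairB, ib); ids <- c(ids, p)
        break
      }
    }
  }
  if (length(ids) == 0)
    stop("no patient carries both resections a and b", call. = FALSE)
  caseDf <- do.call(rbind, lapply(seq_along(ids), function(k) {
    x <- sco[, pairA[k]]; y <- sco[, pairB[k]]
    .concordanceRow("case_pair", ids[k], "spearman", spearmanRho(x, y),
                    sum(!is.na(x) & !is.na(y)))
  }))
  markerDf <- do.call(rbind, lapply(rownames(sco), function(m) {
    x <- sco[m, pairA]; y <- sco[m, pairB]
    .concordanceRow("marker", m, "cosine", cosineSimilarity(x, y),
                    sum(!is.na(x) & !is.na(y)))
  }))
  list(case = caseDf, marker = markerDf)
}

#' Kendall tau-b correlations of markers with CD8, TIL B7-H3 and vital status
#'
#' Computes, within one tumor component: tau-b between CD8 density and each
#' marker's composite score; between the TIL B7-H3 category and each marker
#' score; between binarized vital status and each marker score; and between
#' vital status and the TIL markers (plus CD8 vs TIL B7-H3). Vital status is
#' binarized as 1 = alive and 0 = dead, pooling death from disease with
#' unrelated death and excluding unknowns.
#'
#' @param cohort An [IHCCohort]; duplicate blocks are averaged first.
#' @param component Tumor component to correlate within.
#' @return `data.frame`: var_a, var_b, method, value, n_used, undefined.
#' @export
covariateCorrelations <- function(cohort, component) {
  cohort <- collapseBlocks(cohort)
  sel <- .selectComponent(cohort, component)
  cd <- SummarizedExperiment::colData(cohort)[sel, , drop = FALSE]
  sco <- scores(cohort)[, sel, drop = FALSE]
  cd8 <- as.numeric(cd$cd8_density)
  til <- as.numeric(cd$til_b7h3)
  vital <- ifelse(cd$vital_status == "alive", 1,
                  ifelse(cd$vital_status %in%
                           c("death_from_disease", "death_unrelated"), 0, NA))
  row <- function(va, vb, x, y) {
    n <- sum(!is.na(x) & !is.na(y))
    data.frame(var_a = va, var_b = vb, method = "kendall_tau_b",
               value = kendallTauB(x, y), n_used = n,
               undefined = is.na(kendallTauB(x, y)),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(rownames(sco), function(m) row("cd8_density", m, cd8, sco[m, ])),
    lapply(rownames(sco), function(m) row("til_b7h3", m, til, sco[m, ])),
    lapply(rownames(sco), function(m) row("vital_status", m, vital, sco[m, ])),
    list(row("cd8_density", "til_b7h3", cd8, til),
         row("vital_status", "til_b7h3", vital, til),
         row("vital_status", "til_pdl1", vital, as.numeric(cd$til_pdl1)),
         row("vital_status", "til_pdl2", vital, as.numeric(cd$til_pdl2)))
  ))
  rownames(out) <- NULL
  out
}
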