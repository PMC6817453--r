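# Composite IHC scoring, dual-block averaging, positivity calls and
# per-marker / TIL summaries.

#' Composite IHC score
#'
#' The final reported score for a marker in one tumor component is the
#' product of the percent-positive tumor-cell category (0-4) and the
#' staining intensity (0-3), ranging from 0 to 12.
#'
#' @param percentCategory Integer vector in `0:4`.
#' @param intensity Integer vector in `0:3`.
#' @return Numeric vector of products; `NA` propagates.
#' @export
#' @examples
#' compositeScore(4, 3)  # 12
#' compositeScore(2, 3)  # 6
compositeScore <- function(percentCategory, intensity) {
  bad <- !is.na(percentCategory) & !percentCategory %in% 0:4
  if (any(bad)) stop("percent_category out of range", call. = FALSE)
  bad <- !is.na(intensity) & !intensity %in% 0:3
  if (any(bad)) stop("intensity out of range", call. = FALSE)
  as.numeric(percentCategory) * as.numeric(intensity)
}

#' Average composite scores over duplicate tumor blocks
#'
#' For specimens with two stained tumor blocks, the per-marker scores of the
#' blocks are averaged. A single block passes through unchanged; an
#' all-missing input stays missing; mixed missing/non-missing blocks are an
#' upstream data problem and raise an error.
#'
#' @param blockScores Numeric vector of per-block scores for one
#'   (specimen, marker), length >= 1.
#' @return Scalar mean (possibly non-integer), or `NA` if all missing.
#' @export
#' @examples
#' averageBlocks(c(8, 4))  # 6
averageBlocks <- function(blockScores) {
  if (length(blockScores) < 1) stop("no block scores supplied", call. = FALSE)
  nas <- is.na(blockScores)
  if (all(nas)) return(NA_real_)
  if (any(nas))
    stop("mixed missing/non-missing block scores; resolve upstream", call. = FALSE)
  mean(blockScores)
}

#' Collapse duplicate tumor blocks by averaging
#'
#' Groups records by (patient, resection, component) and averages the
#' percent, intensity and score assays over duplicate blocks. Specimen-level
#' covariates are taken from the first block. The result is flagged
#' `blocks_averaged`, which relaxes the integer product invariant (an
#' averaged composite such as 0.5 is legal and still counts as positive).
#'
#' @param cohort An [IHCCohort].
#' @return An [IHCCohort] with one column per (patient, resection,
#'   component); unchanged (apart from the flag) if no duplicates exist.
#' @export
collapseBlocks <- function(cohort) {
  if (blocksAveraged(cohort)) return(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  key <- paste(cd$patient_id, cd$resection_label, cd$component, sep = "|")
  groups <- split(seq_len(ncol(cohort)), factor(key, levels = unique(key)))
  collapse <- function(m) {
    vapply(groups, function(idx) apply(m[, idx, drop = FALSE], 1, averageBlocks),
           numeric(nrow(m)))
  }
  first <- vapply(groups, `[`, integer(1), 1)
  newcd <- as.data.frame(cd[first, , drop = FALSE])
  newcd$block_id <- vapply(groups, function(idx)
    paste(cd$block_id[idx], collapse = "+"), character(1))
  pct <- collapse(SummarizedExperiment::assay(cohort, "percent"))
  int <- collapse(SummarizedExperiment::assay(cohort, "intensity"))
  sco <- collapse(SummarizedExperiment::assay(cohort, "score"))
  if (ncol(cohort) == 0) {
    pct <- int <- sco <- matrix(numeric(), 10, 0,
                                dimnames = list(markerPanel(), NULL))
  }
  colnames(pct) <- colnames(int) <- colnames(sco) <- NULL
  rownames(pct) <- rownames(int) <- rownames(sco) <- markerPanel()
  rownames(newcd) <- NULL
  IHCCohort(pct, int, newcd, score = sco, blocksAveraged = TRUE)
}

#' Call marker positivity from a composite score
#'
#' A component is positive for a marker iff its composite score is strictly
#' greater than 0; the negative category is exactly 0. Post-averaging
#' fractional scores (e.g. 0.5) therefore count as positive. Missing
#' propagates.
#'
#' @param composite Numeric vector in \[0, 12\] or `NA`.
#' @return Character vector in `{"positive", "negative", NA}`.
#' @export
#' @examples
#' callPositivity(c(0, 0.5, 12, NA))
callPositivity <- function(composite) {
  bad <- !is.na(composite) & (composite < 0 | composite > 12)
  if (any(bad)) stop("composite score outside [0,12]", call. = FALSE)
  ifelse(is.na(composite), NA_character_,
         ifelse(composite > 0, "positive", "negative"))
}

.selectComponent <- function(cohort, component, stratum = NULL) {
  cd <- SummarizedExperiment::colData(cohort)
  sel <- cd$component == component
  if (!is.null(stratum)) {
    for (nm in names(stratum))
      sel <- sel & !is.na(cd[[nm]]) & cd[[nm]] == stratum[[nm]]
  }
  which(sel)
}

#' Summarize one marker in one tumor component
#'
#' Counts exclude unscorable (`NA`) records. `pct_positive` is
#' `100 * n_positive / n_scored`. The reported `mean_score` is, by default,
#' the mean composite over positive records only; set
#' `meanOver = "scored"` to average over all scored records instead (the
#' denominator convention is a genuine ambiguity in this kind of report, so
#' both are available).
#'
#' @param cohort An [IHCCohort]; duplicate blocks are averaged first.
#' @param marker Marker display name from [markerPanel()].
#' @param component One of `"in_situ"`, `"invasive"`, `"metastatic"`.
#'   Metastatic records are never pooled into the other components.
#' @param stratum Optional named list of covariate filters,
#'   e.g. `list(origin = "primary")`.
#' @param meanOver `"positive"` (default) or `"scored"`.
#' @return One-row `data.frame`: marker, component, stratum, n_scored,
#'   n_positive, pct_positive, mean_score.
#' @export
summarizeMarker <- function(cohort, marker, component,
                            stratum = NULL,
                            meanOver = c("positive", "scored")) {
  meanOver <- match.arg(meanOver)
  if (!marker %in% markerPanel())
    stop("unknown marker: ", marker, call. = FALSE)
  cohort <- collapseBlocks(cohort)
  sel <- .selectComponent(cohort, component, stratum)
  v <- scores(cohort)[marker, sel]
  nScored <- sum(!is.na(v))
  if (nScored == 0)
    stop("no scored records for ", marker, " in component ", component,
         call. = FALSE)
  nPos <- sum(v > 0, na.rm = TRUE)
  meanScore <- if (meanOver == "positive") {
    if (nPos > 0) mean(v[!is.na(v) & v > 0]) else NA_real_
  } else {
    mean(v, na.rm = TRUE)
  }
  data.frame(
    marker = marker, component = component,
    stratum = if (is.null(stratum)) NA_character_ else
      paste(names(stratum), unlist(stratum), sep = "=", collapse = ";"),
    n_scored = nScored, n_positive = nPos,
    pct_positive = 100 * nPos / nScored,
    mean_score = meanScore,
    stringsAsFactors = FALSE
  )
}

#' Summarize every panel marker in one component
#'
#' @inheritParams summarizeMarker
#' @param markers Markers to summarize; defaults to the full panel. Markers
#'   with no scored record in the component are skipped with a message.
#' @return `data.frame`, one row per marker, as in [summarizeMarker()].
#' @export
summarizeMarkers <- function(cohort, component, markers = markerPanel(),
                             stratum = NULL,
                             meanOver = c("positive", "scored")) {
  meanOver <- match.arg(meanOver)
  cohort <- collapseBlocks(cohort)
  out <- lapply(markers, function(m) {
    tryCatch(summarizeMarker(cohort, m, component, stratum, meanOver),
             error = function(e) { message(conditionMessage(e)); NULL })
  })
  do.call(rbind, out)
}

#' Summarize the TIL marker fields
#'
#' TIL fields are specimen-level (shared across the components of one
#' resection), so records are deduplicated to one per (patient, resection)
#' before counting. Binary TIL markers (B7-H4, PD-L1, PD-L2) are counted
#' positive/negative; TIL B7-H3 carries a 0-4 percent category and is
#' additionally summarized by its median category.
#'
#' @param cohort An [IHCCohort].
#' @return `data.frame`: til_marker, n_scored, n_positive, pct_positive,
#'   median_category (`NA` for the binary markers).
#' @export
summarizeTIL <- function(cohort) {
  cd <- SummarizedExperiment::colData(cohort)
  key <- paste(cd$patient_id, cd$resection_label, sep = "|")
  first <- !duplicated(key)
  one <- function(x, ordinal = FALSE) {
    x <- as.numeric(x[first])
    n <- sum(!is.na(x))
    if (n == 0) warning("all TIL values missing", call. = FALSE)
    nPos <- sum(x > 0, na.rm = TRUE)
    data.frame(
      n_scored = n, n_positive = nPos,
      pct_positive = if (n > 0) 100 * nPos / n else NA_real_,
      median_category = if (ordinal && n > 0)
        stats::median(x, na.rm = TRUE) else NA_real_
    )
  }
  out <- rbind(
    cbind(til_marker = "TIL B7-H3", one(cd$til_b7h3, ordinal = TRUE)),
    cbind(til_marker = "TIL B7-H4", one(cd$til_b7h4)),
    cbind(til_marker = "TIL PD-L1", one(cd$til_pdl1)),
    cbind(til_marker = "TIL PD-L2", one(cd$til_pdl2))
  )
  rownames(out) <- NULL
  out
}
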