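# Joint-positivity (coexpression) classification and tabulation.

#' Classify one case's joint positivity over a marker set
#'
#' A case is assigned exactly one coexpression category per marker set: if
#' any marker in the set is unscorable the case is `"NA"` (no remaining
#' tumor in the serial section); otherwise the category names the positive
#' subset in panel order (e.g. `"B7-H3/B7-H4"`), or is `"negative"` when no
#' marker in the set is positive.
#'
#' @param positivity Named vector over markers with values `"positive"`,
#'   `"negative"` or `NA` (as from [callPositivity()]); logicals are
#'   accepted.
#' @param markerSet Ordered character vector of markers to classify over.
#' @return Single category label.
#' @export
#' @examples
#' classifyCase(c("B7-H3" = "positive", "B7-H4" = "positive",
#'                "PD-L1" = "negative"),
#'              c("B7-H3", "B7-H4", "PD-L1"))
classifyCase <- function(positivity, markerSet) {
  if (length(markerSet) == 0) stop("empty marker set", call. = FALSE)
  if (is.logical(positivity))
    positivity <- ifelse(is.na(positivity), NA_character_,
                         ifelse(positivity, "positive", "negative"))
  miss <- setdiff(markerSet, names(positivity))
  if (length(miss))
    stop("marker not in positivity map: ", paste(miss, collapse = ", "),
         call. = FALSE)
  p <- positivity[markerSet]
  if (anyNA(p)) return("NA")
  pos <- markerSet[p == "positive"]
  if (length(pos) == 0) "negative" else paste(pos, collapse = "/")
}

# canonical display order for category labels: larger positive subsets
# first, then panel order within a size, then "negative", then "NA"
.categoryOrder <- function(labels, markerSet) {
  subsets <- unlist(lapply(rev(seq_along(markerSet)), function(k) {
    idx <- utils::combn(seq_along(markerSet), k, simplify = FALSE)
    vapply(idx, function(i) paste(markerSet[sort(i)], collapse = "/"),
           character(1))
  }))
  ord <- c(subsets, "negative", "NA")
  labels[order(match(labels, ord))]
}

#' Tabulate coexpression categories in one component
#'
#' Classifies every case of a component over `markerSet` (see
#' [classifyCase()]) and tabulates category counts and percentages. By
#' default the denominator is all cases carrying the component, so `"NA"`
#' cases count in the denominator; set `denominator = "scored"` to restrict
#' to fully scored cases.
#'
#' @param cohort An [IHCCohort]; duplicate blocks are averaged first.
#' @param markerSet Ordered character vector of panel markers.
#' @param component Tumor component to tabulate.
#' @param strata Optional covariate name; the table is then computed per
#'   level with stratum-specific denominators.
#' @param denominator `"all"` (default) or `"scored"`.
#' @return `data.frame`: marker_set, component, stratum, category, n, pct.
#'   Category counts sum to the denominator within each stratum.
#' @export
tabulateCoexpression <- function(cohort, markerSet, component,
                                 strata = NULL,
                                 denominator = c("all", "scored")) {
  denominator <- match.arg(denominator)
  miss <- setdiff(markerSet, markerPanel())
  if (length(miss))
    stop("marker not in panel: ", paste(miss, collapse = ", "), call. = FALSE)
  cohort <- collapseBlocks(cohort)
  sel <- .selectComponent(cohort, component)
  if (length(sel) == 0)
    stop("no cases with component ", component, call. = FALSE)
  sco <- scores(cohort)[markerSet, sel, drop = FALSE]
  labels <- vapply(seq_along(sel), function(j)
    classifyCase(stats::setNames(callPositivity(sco[, j]), rownames(sco)),
                 markerSet), character(1))
  cd <- SummarizedExperiment::colData(cohort)[sel, , drop = FALSE]

  tab1 <- function(lab, stratum) {
    if (denominator == "scored") lab <- lab[lab != "NA"]
    denom <- length(lab)
    cnt <- table(lab)
    cats <- .categoryOrder(names(cnt), markerSet)
    data.frame(
      marker_set = paste(markerSet, collapse = "/"),
      component = component, stratum = stratum,
      category = cats, n = as.integer(cnt[cats]),
      pct = 100 * as.integer(cnt[cats]) / denom,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(strata)) {
    out <- tab1(labels, NA_character_)
  } else {
    lv <- unique(as.character(cd[[strata]]))
    out <- do.call(rbind, lapply(lv, function(l)
      tab1(labels[cd[[strata]] == l], paste0(strata, "=", l))))
  }
  rownames(out) <- NULL
  out
}
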