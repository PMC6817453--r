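#' IHCCohort: specimen-level IHC cohort container
#'
#' An `IHCCohort` is a [SummarizedExperiment::SummarizedExperiment] with one
#' row per panel marker (see [markerPanel()]) and one column per specimen
#' record, i.e. per unique (patient, resection, block, tumor component)
#' tuple. Three assays are carried:
#' \describe{
#'   \item{`percent`}{percent-positive tumor-cell category, ordinal 0-4
#'     (0 = negative, 1 = 1-25\%, 2 = 26-50\%, 3 = 51-75\%, 4 = 76-100\%).}
#'   \item{`intensity`}{staining intensity, ordinal 0-3 (negative, weak,
#'     moderate, strong).}
#'   \item{`score`}{composite score, the product of the two, in \[0, 12\];
#'     non-integer values can only arise after dual-block averaging.}
#' }
#' `NA` in all three assays means no scorable tumor remained in the serial
#' section. `colData` holds the clinical covariates, the TIL marker fields
#' (`til_b7h3` ordinal 0-4; `til_b7h4`/`til_pdl1`/`til_pdl2` binary) and the
#' CD8 density in cells/mm^2. `metadata(x)$blocks_averaged` records whether
#' duplicate tumor blocks have been collapsed by averaging (see
#' [collapseBlocks()]), which relaxes the product invariant.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [readCohort()], [writeCohort()], [validateCohort()],
#'   [generateCohort()]
#' @aliases IHCCohort-class
#' @export
setClass("IHCCohort", contains = "SummarizedExperiment")

#' Construct an IHCCohort from assay matrices
#'
#' @param percent,intensity Numeric marker-by-specimen matrices with
#'   `rownames` equal to [markerPanel()].
#' @param colData A `data.frame` or `DataFrame` with the specimen-level
#'   covariate columns (`patient_id`, `resection_label`, `block_id`,
#'   `component`, `sex`, `age`, `extent`, `origin`, `site`, `treatment`,
#'   `vital_status`, `cd8_density`, `til_b7h3`, `til_b7h4`, `til_pdl1`,
#'   `til_pdl2`).
#' @param score Composite-score matrix; defaults to the elementwise product
#'   of `percent` and `intensity`.
#' @param blocksAveraged Logical; `TRUE` for cohorts whose duplicate blocks
#'   have already been averaged (scores need not be products then).
#' @return A validated [IHCCohort] object.
#' @export
#' @examples
#' pct <- matrix(0, 10, 0, dimnames = list(markerPanel(), NULL))
#' emptyCohort <- IHCCohort(pct, pct, .emptyCovariates())
#' ncol(emptyCohort)
IHCCohort <- function(percent, intensity, colData,
                      score = percent * intensity,
                      blocksAveraged = FALSE) {
  percent <- as.matrix(percent)
  intensity <- as.matrix(intensity)
  score <- as.matrix(score)
  if (is.null(rownames(percent)))
    rownames(percent) <- rownames(intensity) <- rownames(score) <- markerPanel()
  cd <- S4Vectors::DataFrame(colData, check.names = FALSE)
  for (col in intersect(c("age", "cd8_density", "til_b7h3", "til_b7h4",
                          "til_pdl1", "til_pdl2"), colnames(cd)))
    cd[[col]] <- as.numeric(cd[[col]])
  if (ncol(percent) > 0) {
    ids <- .specimenIds(cd)
    colnames(percent) <- colnames(intensity) <- colnames(score) <- ids
    rownames(cd) <- ids
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(percent = percent, intensity = intensity, score = score),
    colData = cd,
    metadata = list(blocks_averaged = isTRUE(blocksAveraged))
  )
  obj <- new("IHCCohort", se)
  methods::validObject(obj)
  obj
}

# canonical specimen record label: patient[, resection][.block].component
.specimenIds <- function(cd) {
  res <- ifelse(cd$resection_label == "none", "", as.character(cd$resection_label))
  paste0(cd$patient_id, res, ".", cd$block_id, ".", cd$component)
}

#' An empty covariate table with the declared schema
#'
#' Mainly useful for constructing empty or toy cohorts in examples/tests.
#' @return A zero-row `data.frame` with the specimen covariate columns.
#' @export
.emptyCovariates <- function() {
  df <- data.frame(
    patient_id = character(), resection_label = character(),
    block_id = character(), component = character(),
    sex = character(), age = numeric(), extent = character(),
    origin = character(), site = character(), treatment = character(),
    vital_status = character(), cd8_density = numeric(),
    til_b7h3 = numeric(), til_b7h4 = numeric(), til_pdl1 = numeric(),
    til_pdl2 = numeric(), stringsAsFactors = FALSE
  )
  df
}

setValidity("IHCCohort", function(object) {
  v <- validateCohort(object)
  if (length(v) == 0) TRUE else v
})

#' @describeIn IHCCohort-accessors composite-score assay (markers x records)
#' @export
scores <- function(x) SummarizedExperiment::assay(x, "score")

#' Accessors for IHCCohort
#'
#' Small accessors over the assay and covariate slots; prefer these over
#' direct slot access.
#'
#' @param x An [IHCCohort].
#' @name IHCCohort-accessors
#' @return The requested assay matrix or covariate vector.
NULL

#' @describeIn IHCCohort-accessors percent-positive category assay
#' @export
percentCategory <- function(x) SummarizedExperiment::assay(x, "percent")

#' @describeIn IHCCohort-accessors staining-intensity assay
#' @export
stainIntensity <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @describeIn IHCCohort-accessors patient identifiers per record
#' @export
patientIds <- function(x) as.character(SummarizedExperiment::colData(x)$patient_id)

#' @describeIn IHCCohort-accessors tumor component per record
#' @export
componentLabels <- function(x) as.character(SummarizedExperiment::colData(x)$component)

#' @describeIn IHCCohort-accessors CD8 density (cells/mm^2) per record
#' @export
cd8Density <- function(x) as.numeric(SummarizedExperiment::colData(x)$cd8_density)

#' @describeIn IHCCohort-accessors TRUE once duplicate blocks were averaged
#' @export
blocksAveraged <- function(x) isTRUE(S4Vectors::metadata(x)$blocks_averaged)

setMethod("show", "IHCCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("IHCCohort:", length(unique(cd$patient_id)), "patients,",
      ncol(object), "specimen records\n")
  if (ncol(object) > 0) {
    cat("  components:",
        paste(sprintf("%s=%d", names(table(cd$component)),
                      as.integer(table(cd$component))), collapse = ", "), "\n")
  }
  cat("  markers:", paste(rownames(object), collapse = ", "), "\n")
  cat("  blocks averaged:", blocksAveraged(object), "\n")
})
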