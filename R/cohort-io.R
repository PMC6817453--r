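# CSV import/export and invariant checking for the specimen-level schema.
#
# Dialect: UTF-8, comma-separated, one header row, literal "NA" for missing.
# One row per (patient, resection, block, component) record; per-marker
# column triplets <token>_pct, <token>_int, <token>_score (score optional on
# input, always written on output).

.markerCols <- function(what = c("pct", "int", "score")) {
  what <- match.arg(what)
  paste0(unname(.MARKER_TOKENS), "_", what)
}

#' Validate a cohort against the schema invariants
#'
#' Reporting counterpart of the class validity method: returns a character
#' vector of human-readable violations (empty when the cohort is valid),
#' each naming the offending record and rule. Checked rules include assay
#' category ranges, the pre-averaging product rule (composite = percent x
#' intensity, hence in the attainable set `{0,1,2,3,4,6,8,9,12}`), consistent
#' missingness across the three assays, record-tuple uniqueness, resection
#' labeling (a record labeled `b` requires an `a` for the same patient),
#' nonnegative CD8 density, and the declared covariate vocabularies.
#'
#' @param cohort An [IHCCohort] (or the `SummarizedExperiment` inside one).
#' @return Character vector of violation descriptions; `character(0)` if
#'   the cohort is valid.
#' @export
#' @examples
#' validateCohort(generateCohort(generatorConfig(nPatients = 4)))
validateCohort <- function(cohort) {
  v <- character()
  pct <- SummarizedExperiment::assay(cohort, "percent")
  int <- SummarizedExperiment::assay(cohort, "intensity")
  sco <- SummarizedExperiment::assay(cohort, "score")
  cd <- SummarizedExperiment::colData(cohort)
  averaged <- isTRUE(S4Vectors::metadata(cohort)$blocks_averaged)

  if (!identical(rownames(pct), markerPanel()))
    v <- c(v, "assay rows must be the canonical marker panel")
  need <- setdiff(.COVARIATE_COLS, colnames(cd))
  if (length(need))
    return(c(v, paste0("missing covariate column '", need, "'")))

  ids <- if (!is.null(colnames(sco))) colnames(sco) else as.character(seq_len(ncol(sco)))

  # assay-level checks, reported per record/marker
  for (j in seq_len(ncol(sco))) {
    for (i in seq_len(nrow(sco))) {
      p <- pct[i, j]; k <- int[i, j]; s <- sco[i, j]
      mk <- rownames(sco)[i]
      nas <- c(is.na(p), is.na(k), is.na(s))
      if (any(nas) && !all(nas)) {
        v <- c(v, sprintf("record %s, marker %s: inconsistent missingness across assays",
                          ids[j], mk))
        next
      }
      if (all(nas)) next
      if (s < 0 || s > 12)
        v <- c(v, sprintf("record %s, marker %s: composite outside [0,12]", ids[j], mk))
      if (!averaged) {
        if (!p %in% 0:4)
          v <- c(v, sprintf("record %s, marker %s: percent_category out of range", ids[j], mk))
        if (!k %in% 0:3)
          v <- c(v, sprintf("record %s, marker %s: intensity out of range", ids[j], mk))
        if (!isTRUE(all.equal(s, p * k)) ||
            !any(abs(s - attainableCompositeScores()) < 1e-9))
          v <- c(v, sprintf(
            "record %s, marker %s: composite %s is not an attainable percent x intensity product",
            ids[j], mk, format(s)))
      }
    }
  }

  # record uniqueness
  key <- paste(cd$patient_id, cd$resection_label, cd$block_id, cd$component, sep = "|")
  if (anyDuplicated(key))
    v <- c(v, sprintf("duplicate (patient, resection, block, component) record: %s",
                      unique(key[duplicated(key)])))

  # resection b requires a
  byPat <- split(as.character(cd$resection_label), as.character(cd$patient_id))
  bad <- names(byPat)[vapply(byPat, function(r) "b" %in% r && !"a" %in% r, logical(1))]
  if (length(bad))
    v <- c(v, sprintf("patient %s: resection 'b' present without 'a'", bad))

  # covariate vocabularies
  chk <- function(col, set) {
    x <- as.character(cd[[col]])
    bad <- which(!is.na(x) & !x %in% set)
    if (length(bad))
      sprintf("record %s: %s '%s' not in {%s}", ids[bad], col, x[bad],
              paste(set, collapse = ", "))
    else character()
  }
  v <- c(v, chk("component", .COMPONENTS), chk("resection_label", .RESECTIONS),
         chk("sex", .SEX), chk("extent", .EXTENT), chk("origin", .ORIGIN),
         chk("site", .SITE), chk("vital_status", .VITAL))

  cd8 <- as.numeric(cd$cd8_density)
  bad <- which(!is.na(cd8) & cd8 < 0)
  if (length(bad))
    v <- c(v, sprintf("record %s: cd8_density negative", ids[bad]))

  tb <- as.numeric(cd$til_b7h3)
  bad <- which(!is.na(tb) & !tb %in% 0:4)
  if (length(bad))
    v <- c(v, sprintf("record %s: til_b7h3 out of range", ids[bad]))
  for (col in c("til_b7h4", "til_pdl1", "til_pdl2")) {
    x <- as.numeric(cd[[col]])
    bad <- which(!is.na(x) & !x %in% c(0, 1))
    if (length(bad))
      v <- c(v, sprintf("record %s: %s not binary", ids[bad], col))
  }
  v
}

#' Flatten an IHCCohort to the specimen-level data.frame schema
#'
#' @param cohort An [IHCCohort].
#' @return `data.frame` with one row per record: the covariate columns, then
#'   `<marker>_pct`, `<marker>_int`, `<marker>_score` per panel marker.
#' @seealso [writeCohort()]
#' @export
cohortToDataFrame <- function(cohort) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  df <- cd[, .COVARIATE_COLS, drop = FALSE]
  pct <- t(SummarizedExperiment::assay(cohort, "percent"))
  int <- t(SummarizedExperiment::assay(cohort, "intensity"))
  sco <- t(SummarizedExperiment::assay(cohort, "score"))
  colnames(pct) <- .markerCols("pct")
  colnames(int) <- .markerCols("int")
  colnames(sco) <- .markerCols("score")
  out <- cbind(df, as.data.frame(pct), as.data.frame(int), as.data.frame(sco))
  rownames(out) <- NULL
  out
}

#' Build an IHCCohort from a specimen-level data.frame
#'
#' Performs the hard schema checks the CSV reader relies on: any missing
#' declared column aborts naming the column; any out-of-range percent
#' category or intensity aborts naming the row and marker.
#'
#' @param df `data.frame` in the schema written by [cohortToDataFrame()];
#'   the `<marker>_score` columns are optional and recomputed when absent.
#' @return An [IHCCohort].
#' @export
cohortFromDataFrame <- function(df) {
  need <- c(.COVARIATE_COLS, .markerCols("pct"), .markerCols("int"))
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("schema mismatch: missing column '", miss[1], "'", call. = FALSE)

  toks <- unname(.MARKER_TOKENS)
  n <- nrow(df)
  getm <- function(cols) {
    m <- t(as.matrix(as.data.frame(lapply(df[cols], as.numeric))))
    dimnames(m) <- list(markerPanel(), NULL)
    if (n == 0) m <- matrix(numeric(), 10, 0, dimnames = list(markerPanel(), NULL))
    m
  }
  pct <- getm(paste0(toks, "_pct"))
  int <- getm(paste0(toks, "_int"))

  hasScore <- all(.markerCols("score") %in% colnames(df))
  sco <- if (hasScore) getm(paste0(toks, "_score")) else pct * int
  averaged <- hasScore &&
    any(abs(sco - pct * int) > 1e-9 | (pct %% 1 != 0), na.rm = TRUE)

  if (!averaged) {
    for (j in seq_len(n)) for (i in seq_len(10)) {
      if (!is.na(pct[i, j]) && !pct[i, j] %in% 0:4)
        stop(sprintf("row %d, marker %s: percent_category out of range",
                     j, markerPanel()[i]), call. = FALSE)
      if (!is.na(int[i, j]) && !int[i, j] %in% 0:3)
        stop(sprintf("row %d, marker %s: intensity out of range",
                     j, markerPanel()[i]), call. = FALSE)
    }
  }

  cd <- df[, .COVARIATE_COLS, drop = FALSE]
  for (col in c("patient_id", "resection_label", "block_id", "component",
                "sex", "extent", "origin", "site", "treatment", "vital_status"))
    cd[[col]] <- as.character(cd[[col]])
  for (col in c("age", "cd8_density", "til_b7h3", "til_b7h4", "til_pdl1", "til_pdl2"))
    cd[[col]] <- as.numeric(cd[[col]])
  IHCCohort(pct, int, cd, score = sco, blocksAveraged = averaged)
}

#' Read a specimen-level cohort CSV
#'
#' @param path Path to a CSV in the declared dialect (UTF-8, comma-separated,
#'   literal `NA` for missing, one row per specimen record).
#' @return A validated [IHCCohort]; row count is preserved as column count.
#' @export
#' @seealso [writeCohort()], [cohortFromDataFrame()]
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                        check.names = FALSE, fileEncoding = "UTF-8")
  cohortFromDataFrame(df)
}

#' Write a cohort to the specimen-level CSV schema
#'
#' The output round-trips losslessly through [readCohort()]; missing cells
#' are written as the literal `NA`.
#'
#' @param cohort An [IHCCohort].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  df <- cohortToDataFrame(cohort)
  utils::write.csv(df, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}
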