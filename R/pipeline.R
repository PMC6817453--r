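# End-to-end pipeline driver and in-code worked-example fixtures.

#' RunConfig: end-to-end pipeline configuration
#'
#' Built with [runConfig()]; consumed by [runPipeline()].
#'
#' @aliases RunConfig-class
#' @export
setClass("RunConfig", representation(
  inputPath = "character",
  generator = "GeneratorConfig",
  outputDir = "character",
  seed = "integer",
  nIter = "integer",
  fdr = "numeric",
  meanOver = "character",
  denominator = "character",
  contrasts = "data.frame",
  clusterComponents = "character"
))

setValidity("RunConfig", function(object) {
  v <- character()
  if (!(object@fdr > 0 && object@fdr < 1)) v <- c(v, "fdr must lie in (0, 1)")
  if (object@nIter < 1) v <- c(v, "nIter must be >= 1")
  if (!object@meanOver %in% c("positive", "scored"))
    v <- c(v, "meanOver must be 'positive' or 'scored'")
  if (!object@denominator %in% c("all", "scored"))
    v <- c(v, "denominator must be 'all' or 'scored'")
  if (length(v)) v else TRUE
})

.DEFAULT_CONTRASTS <- data.frame(
  covariate = c("origin", "site", "sex"),
  level_a = c("primary", "vulvar", "female"),
  level_b = c("secondary", "perianal", "male"),
  stringsAsFactors = FALSE
)

#' Build a pipeline run configuration
#'
#' @param outputDir Directory for all stage outputs (created if needed).
#' @param inputPath Optional cohort CSV; when `NA` (default) a cohort is
#'   generated from `generator`.
#' @param generator A [GeneratorConfig]; default [presetPaperLike()].
#' @param seed Root seed for all pipeline randomness.
#' @param nIter Permutation iterations for the association screen.
#' @param fdr FDR threshold.
#' @param meanOver Mean-score denominator convention (see
#'   [summarizeMarker()]).
#' @param denominator Coexpression denominator convention (see
#'   [tabulateCoexpression()]).
#' @param contrasts Covariate contrasts for the association screen.
#' @param clusterComponents Components to cluster (default `"in_situ"`).
#' @return A validated [RunConfig].
#' @export
runConfig <- function(outputDir, inputPath = NA_character_,
                      generator = presetPaperLike(), seed = 1L,
                      nIter = 1000L, fdr = 0.05,
                      meanOver = "positive", denominator = "all",
                      contrasts = .DEFAULT_CONTRASTS,
                      clusterComponents = "in_situ") {
  new("RunConfig", inputPath = inputPath, generator = generator,
      outputDir = outputDir, seed = as.integer(seed),
      nIter = as.integer(nIter), fdr = fdr, meanOver = meanOver,
      denominator = denominator, contrasts = contrasts,
      clusterComponents = clusterComponents)
}

.MARKER_SETS <- list(
  b7 = c("B7-H3", "B7-H4", "PD-L1"),
  cta = c("MAGE-A", "NY-ESO-1"),
  ck = c("CK7", "CK20")
)

#' Run the full analysis pipeline
#'
#' Stages: read or synthesize the cohort; average duplicate blocks; write
#' marker and TIL summaries, coexpression tables, the association screen,
#' concordance statistics and the clustered score matrix with dendrograms.
#' Writes six output files plus a manifest (`manifest.json`) that echoes
#' the configuration and the per-stage record counts; rerunning with the
#' same configuration and seed reproduces every output byte for byte.
#'
#' @param config A [RunConfig].
#' @return The manifest, invisibly (also written as JSON).
#' @export
runPipeline <- function(config) {
  methods::validObject(config)
  dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config@outputDir, f)
  log <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

  cohort <- if (!is.na(config@inputPath)) {
    log("input", "reading %s", config@inputPath)
    readCohort(config@inputPath)
  } else {
    log("synth", "generating cohort (n=%d, seed=%d)",
        config@generator@nPatients, config@seed)
    generateCohort(config@generator, seed = config@seed)
  }
  cohort <- collapseBlocks(cohort)
  comps <- intersect(.COMPONENTS, unique(componentLabels(cohort)))
  log("score", "%d records after block averaging", ncol(cohort))

  # marker + TIL summary
  ms <- do.call(rbind, lapply(comps, function(cp)
    summarizeMarkers(cohort, cp, meanOver = config@meanOver)))
  ms$median_category <- NA_real_
  til <- summarizeTIL(cohort)
  til <- data.frame(marker = til$til_marker, component = "til",
                    stratum = NA_character_, n_scored = til$n_scored,
                    n_positive = til$n_positive,
                    pct_positive = til$pct_positive,
                    mean_score = NA_real_,
                    median_category = til$median_category,
                    stringsAsFactors = FALSE)
  utils::write.csv(rbind(ms, til), out("marker_summary.csv"),
                   row.names = FALSE, na = "NA")
  log("summarize", "%d summary rows", nrow(ms) + nrow(til))

  # coexpression
  co <- do.call(rbind, lapply(comps[comps != "metastatic"], function(cp)
    do.call(rbind, lapply(.MARKER_SETS, function(set)
      tabulateCoexpression(cohort, set, cp,
                           denominator = config@denominator)))))
  utils::write.csv(co, out("coexpression.csv"), row.names = FALSE, na = "NA")
  log("coexpress", "%d category rows", nrow(co))

  # association screen
  as_ <- do.call(rbind, lapply(comps[comps != "metastatic"], function(cp)
    runAssociationScreen(cohort, config@contrasts, cp,
                         nIter = config@nIter, seed = config@seed,
                         fdr = config@fdr)))
  utils::write.csv(as_, out("associations.csv"), row.names = FALSE, na = "NA")
  log("associate", "%d comparisons, %d eligible", nrow(as_), sum(as_$eligible))

  # concordance
  conc <- list()
  cc <- tryCatch(componentConcordance(cohort), error = function(e) NULL)
  if (!is.null(cc)) conc <- c(conc, list(cc$case, cc$marker))
  rc <- tryCatch(resectionConcordance(cohort), error = function(e) NULL)
  if (!is.null(rc)) conc <- c(conc, list(
    transform(rc$case, unit = "resection_pair"), rc$marker))
  cv <- covariateCorrelations(cohort, comps[1])
  conc <- c(conc, list(data.frame(unit = "covariate",
                                  id = paste(cv$var_a, cv$var_b, sep = "~"),
                                  method = cv$method, value = cv$value,
                                  n_used = cv$n_used,
                                  undefined = cv$undefined)))
  conc <- do.call(rbind, conc)
  utils::write.csv(conc, out("concordance.csv"), row.names = FALSE, na = "NA")
  log("concord", "%d concordance rows", nrow(conc))

  # clustering (first requested component; others appended to JSON)
  cl <- suppressWarnings(clusterCohort(cohort, config@clusterComponents[1]))
  utils::write.csv(cbind(marker = rownames(cl@matrix),
                         as.data.frame(cl@matrix)),
                   out("clustered_matrix.csv"), row.names = FALSE, na = "NA")
  dendro <- list(markers = .dendrogramToList(cl@markerDendrogram),
                 cases = .dendrogramToList(cl@caseDendrogram),
                 annotations = cl@annotations)
  jsonlite::write_json(dendro, out("dendrograms.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  log("cluster", "%d markers x %d cases", nrow(cl@matrix), ncol(cl@matrix))

  manifest <- list(
    package = "empdpanel",
    seed = config@seed,
    n_iter = config@nIter,
    fdr = config@fdr,
    mean_over = config@meanOver,
    denominator = config@denominator,
    input = if (is.na(config@inputPath)) "generated" else config@inputPath,
    n_patients = length(unique(patientIds(cohort))),
    n_records = ncol(cohort),
    outputs = c("marker_summary.csv", "coexpression.csv", "associations.csv",
                "concordance.csv", "clustered_matrix.csv", "dendrograms.json")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Deterministic worked-example cohort
#'
#' A 49-case, in situ-only cohort whose per-marker positivity pattern is
#' reconstructed from the reference tabulation of coexpression categories:
#' B7 set 3 triple positive (B7-H3/B7-H4/PD-L1), 36 B7-H3/B7-H4 double, 7
#' B7-H3 single, 1 B7-H4 single, 2 negative; CTA set 7 MAGE-A/NY-ESO-1
#' double, 12 MAGE-A single, 1 NY-ESO-1 single, 29 negative; CK set 35 CK7
#' single, 4 CK20 single, 10 double; B2M positive in all 49, MHC-I in 38,
#' PD-L2 in none. Positive components score 8 (category 4 x intensity 2).
#' The joint assignment across sets is arbitrary (only the marginals are
#' known); covariates are filler. No randomness, no missing values.
#'
#' @return An [IHCCohort] with 49 in situ records.
#' @export
workedExampleCohort <- function() {
  n <- 49
  runs <- function(counts) rep(seq_along(counts), counts)
  b7 <- runs(c(3, 36, 7, 1, 2))       # triple, H3/H4, H3, H4, negative
  cta <- runs(c(7, 12, 1, 29))        # double, MAGE-A, NY-ESO-1, negative
  ck <- runs(c(10, 35, 4))            # double, CK7 only, CK20 only
  pos <- matrix(FALSE, 10, n, dimnames = list(markerPanel(), NULL))
  pos["B7-H3", ] <- b7 %in% 1:3
  pos["B7-H4", ] <- b7 %in% c(1, 2, 4)
  pos["PD-L1", ] <- b7 == 1
  pos["MAGE-A", ] <- cta %in% 1:2
  pos["NY-ESO-1", ] <- cta %in% c(1, 3)
  pos["B2M", ] <- TRUE
  pos["MHC-I", ] <- seq_len(n) <= 38
  pos["CK7", ] <- ck %in% 1:2
  pos["CK20", ] <- ck %in% c(1, 3)
  pct <- ifelse(pos, 4, 0)
  int <- ifelse(pos, 2, 0)
  cd <- data.frame(
    patient_id = sprintf("W%02d", seq_len(n)), resection_label = "none",
    block_id = "B1", component = "in_situ", sex = "female", age = 69,
    extent = "in_situ", origin = "primary", site = "vulvar",
    treatment = "none", vital_status = "unknown", cd8_density = 100,
    til_b7h3 = 1, til_b7h4 = 0, til_pdl1 = 1, til_pdl2 = 0,
    stringsAsFactors = FALSE
  )
  IHCCohort(pct, int, cd)
}

.WORKED_EXPECTED <- data.frame(
  check = c("B7-H3 in situ % positive", "B7-H4 in situ % positive",
            "PD-L1 in situ % positive", "MAGE-A in situ % positive",
            "NY-ESO-1 in situ % positive", "CK7 in situ % positive",
            "CK20 in situ % positive",
            "B7 triple-positive %", "B7-H3/B7-H4 double-positive %"),
  expected = c(93.9, 81.6, 6.1, 38.8, 16.3, 91.8, 28.6, 6.1, 73.5),
  stringsAsFactors = FALSE
)

#' Recompute the worked examples and compare to the reference values
#'
#' Runs [summarizeMarker()] and [tabulateCoexpression()] on the
#' [workedExampleCohort()] and compares the marginal percent-positive
#' values and coexpression percentages against the bundled reference
#' tabulation (printed to one decimal, so agreement is checked at 0.05).
#'
#' @return `data.frame`: check, expected, observed, pass.
#' @export
#' @examples
#' reproduceWorkedExamples()
reproduceWorkedExamples <- function() {
  cohort <- workedExampleCohort()
  obs <- c(
    vapply(c("B7-H3", "B7-H4", "PD-L1", "MAGE-A", "NY-ESO-1", "CK7", "CK20"),
           function(m) summarizeMarker(cohort, m, "in_situ")$pct_positive,
           numeric(1)),
    local({
      tab <- tabulateCoexpression(cohort, .MARKER_SETS$b7, "in_situ")
      c(tab$pct[tab$category == "B7-H3/B7-H4/PD-L1"],
        tab$pct[tab$category == "B7-H3/B7-H4"])
    })
  )
  out <- .WORKED_EXPECTED
  out$observed <- round(as.numeric(obs), 1)
  out$pass <- abs(out$observed - out$expected) <= 0.05
  out
}
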