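# Synthetic-cohort generator: emulates the statistical structure the
# downstream analyses assume (marker prevalence per component, composite
# score distributions, component coupling, NA patterns, duplicate blocks,
# repeat resections, clinical covariates, TIL fields, CD8 density).

# deterministic factorization of each attainable nonzero composite into
# (percent category, intensity); broad-staining factorization preferred
.SCORE_FACTORS <- list(
  `1` = c(1, 1), `2` = c(2, 1), `3` = c(3, 1), `4` = c(4, 1),
  `6` = c(3, 2), `8` = c(4, 2), `9` = c(3, 3), `12` = c(4, 3)
)

.DEFAULT_SCORE_DIST <- c(`1` = 0.05, `2` = 0.10, `3` = 0.10, `4` = 0.15,
                         `6` = 0.20, `8` = 0.15, `9` = 0.10, `12` = 0.15)

.DEFAULT_COVARIATE_FREQS <- list(
  sex = c(female = 0.646, male = 0.354),
  extent = c(in_situ = 0.611, invasive = 0.352, metastatic = 0.037),
  origin = c(primary = 0.889, secondary = 0.111),
  site = c(vulvar = 0.463, penile_scrotal = 0.167, perianal = 0.204,
           perineum = 0.093, other = 0.074),
  treatment = c(none = 0.685, aldara = 0.130, aldara_chemotherapy = 0.019,
                aldara_neratinib = 0.037, chemotherapy = 0.056,
                fluorouracil = 0.019, other = 0.056),
  vital_status = c(alive = 0.417, death_from_disease = 0.104,
                   death_unrelated = 0.042, unknown = 0.438)
)

#' GeneratorConfig: parameters of the synthetic-cohort generator
#'
#' See [generatorConfig()] for field semantics and defaults and
#' [presetPaperLike()] for a configuration emulating a published EMPD
#' cohort's composition.
#'
#' @aliases GeneratorConfig-class
#' @export
setClass("GeneratorConfig", representation(
  nPatients = "integer",
  prevalence = "list",
  scoreDist = "list",
  componentConcordance = "numeric",
  covariateFreqs = "list",
  naRate = "numeric",
  dualBlockRate = "numeric",
  secondResectionRate = "numeric",
  bothComponentRate = "numeric",
  cd8Meanlog = "numeric",
  cd8Sdlog = "numeric",
  tilCd8Coupling = "numeric",
  tilB7h3Dist = "numeric",
  tilRates = "numeric",
  effects = "data.frame",
  seed = "integer"
))

setValidity("GeneratorConfig", function(object) {
  v <- character()
  probs <- c(object@componentConcordance, object@naRate, object@dualBlockRate,
             object@secondResectionRate, object@bothComponentRate,
             unlist(object@prevalence), object@tilRates, object@tilB7h3Dist,
             unlist(object@covariateFreqs))
  if (any(probs < 0 | probs > 1))
    v <- c(v, "all probabilities must lie in [0, 1]")
  if (object@nPatients < 0) v <- c(v, "nPatients must be nonnegative")
  for (m in names(object@scoreDist)) {
    sd <- object@scoreDist[[m]]
    if (!identical(names(sd), names(.DEFAULT_SCORE_DIST)))
      v <- c(v, sprintf("scoreDist[%s] must be named over {1,2,3,4,6,8,9,12}", m))
    else if (abs(sum(sd) - 1) > 1e-8)
      v <- c(v, sprintf("scoreDist[%s] must sum to 1", m))
  }
  if (nrow(object@effects) &&
      !all(c("marker", "covariate", "level", "offset") %in%
             colnames(object@effects)))
    v <- c(v, "effects needs columns marker, covariate, level, offset")
  if (length(v)) v else TRUE
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@nPatients, "patients, seed", object@seed, "\n")
})

#' Build a synthetic-cohort generator configuration
#'
#' Defaults describe a generic, realistic EMPD-like cohort: the clinical
#' covariate composition of a published 48-patient cohort, a mildly
#' top-heavy composite-score distribution for positive components, strong
#' in situ/invasive coupling, occasional unscorable components, and a
#' right-skewed lognormal CD8 density.
#'
#' @param nPatients Number of patients (default 48).
#' @param prevalence Named list marker -> probability of positivity; each
#'   entry is either a scalar or a named vector over components
#'   (`in_situ`, `invasive`, `metastatic`; missing components fall back to
#'   `invasive`, then the first entry). Default 0.5 for every marker.
#' @param scoreDist Named list marker -> probability vector over the
#'   attainable nonzero composites `{1,2,3,4,6,8,9,12}`, conditional on
#'   positivity. Markers absent from the list use the package default.
#' @param componentConcordance Copy probability kappa coupling the invasive
#'   to the in situ positivity state of the same case: with probability
#'   kappa the state is copied, otherwise redrawn independently. The
#'   realized probability that the two states agree is
#'   [impliedComponentConcordance()], not kappa itself (independent draws
#'   already agree at rate `p^2 + (1-p)^2`).
#' @param covariateFreqs Named list of category frequency vectors for sex,
#'   extent, origin, site, treatment, vital_status. Patients are allocated
#'   by largest-remainder exact counts, then permuted, so a frequency of
#'   6/48 yields exactly 6 patients at n = 48.
#' @param naRate Probability that a (case, component, marker) is unscorable.
#' @param dualBlockRate Fraction of specimens with two stained tumor blocks
#'   (exact count, rounded).
#' @param secondResectionRate Fraction of patients with resections `a` and
#'   `b` (exact count, rounded).
#' @param bothComponentRate Probability that an invasive-extent specimen
#'   also carries a scorable in situ component.
#' @param cd8Meanlog,cd8Sdlog Lognormal location/scale of CD8 density
#'   (cells/mm^2).
#' @param tilCd8Coupling Added to `cd8Meanlog` per TIL B7-H3 category,
#'   inducing a configurable rank dependence between the two.
#' @param tilB7h3Dist Probability vector over TIL B7-H3 categories 0-4.
#' @param tilRates Named positivity probabilities for the binary TIL
#'   markers `til_b7h4`, `til_pdl1`, `til_pdl2`.
#' @param effects Optional `data.frame` (marker, covariate, level, offset):
#'   patients whose covariate equals `level` get `offset` added to that
#'   marker's positivity prevalence (clamped to \[0, 1\]).
#' @param seed Root seed; [generateCohort()] splits it into per-stage
#'   substreams.
#' @return A validated [GeneratorConfig].
#' @export
generatorConfig <- function(nPatients = 48,
                            prevalence = NULL,
                            scoreDist = list(),
                            componentConcordance = 0.9,
                            covariateFreqs = .DEFAULT_COVARIATE_FREQS,
                            naRate = 0.04,
                            dualBlockRate = 3 / 54,
                            secondResectionRate = 6 / 48,
                            bothComponentRate = 16 / 19,
                            cd8Meanlog = log(150),
                            cd8Sdlog = 0.8,
                            tilCd8Coupling = 0,
                            tilB7h3Dist = c(0.204, 0.45, 0.20, 0.10, 0.046),
                            tilRates = c(til_b7h4 = 0, til_pdl1 = 0.722,
                                         til_pdl2 = 0.074),
                            effects = data.frame(),
                            seed = 1L) {
  if (is.null(prevalence))
    prevalence <- stats::setNames(as.list(rep(0.5, 10)), markerPanel())
  freqs <- .DEFAULT_COVARIATE_FREQS
  freqs[names(covariateFreqs)] <- covariateFreqs
  new("GeneratorConfig",
      nPatients = as.integer(nPatients), prevalence = prevalence,
      scoreDist = scoreDist, componentConcordance = componentConcordance,
      covariateFreqs = freqs, naRate = naRate,
      dualBlockRate = dualBlockRate,
      secondResectionRate = secondResectionRate,
      bothComponentRate = bothComponentRate,
      cd8Meanlog = cd8Meanlog, cd8Sdlog = cd8Sdlog,
      tilCd8Coupling = tilCd8Coupling,
      tilB7h3Dist = tilB7h3Dist / sum(tilB7h3Dist), tilRates = tilRates,
      effects = effects, seed = as.integer(seed))
}

#' Implied probability that component positivity states agree
#'
#' Under the generator's coupling (copy with probability kappa, else an
#' independent redraw at prevalence `p`), the probability that the in situ
#' and invasive states of a case agree is
#' `kappa + (1 - kappa) * (p^2 + (1 - p)^2)`.
#'
#' @param p Positivity prevalence.
#' @param kappa Copy probability (`componentConcordance`).
#' @return Agreement probability.
#' @export
impliedComponentConcordance <- function(p, kappa) {
  kappa + (1 - kappa) * (p^2 + (1 - p)^2)
}

#' Generator preset emulating a published EMPD cohort
#'
#' 48 patients; per-marker in situ / invasive positivity prevalences set to
#' the reference cohort's reported percent-positive marginals (B7-H3 94/90,
#' B7-H4 82/78, PD-L1 6/10, PD-L2 0/0, MAGE-A 39/50, NY-ESO-1 16/20, B2M
#' 100/89, MHC-I 78/79, CK7 92/90, CK20 29/45, in percent); exactly 6
#' secondary-origin patients and 6 two-resection patients at n = 48 and an
#' expected 3 dual-block specimens; origin effects reproducing the
#' preferential expression of B7-H4/CK7 in primary and CK20 in secondary
#' disease; and a positive TIL-B7-H3/CD8 coupling.
#'
#' @return A [GeneratorConfig].
#' @export
presetPaperLike <- function() {
  prevalence <- list(
    "B7-H3"    = c(in_situ = 0.939, invasive = 0.895),
    "B7-H4"    = c(in_situ = 0.816, invasive = 0.778),
    "PD-L1"    = c(in_situ = 0.061, invasive = 0.095),
    "PD-L2"    = c(in_situ = 0,     invasive = 0),
    "MAGE-A"   = c(in_situ = 0.388, invasive = 0.500),
    "NY-ESO-1" = c(in_situ = 0.163, invasive = 0.200),
    "B2M"      = c(in_situ = 1.0,   invasive = 0.889, metastatic = 0),
    "MHC-I"    = c(in_situ = 0.776, invasive = 0.789, metastatic = 0.5),
    "CK7"      = c(in_situ = 0.918, invasive = 0.905),
    "CK20"     = c(in_situ = 0.286, invasive = 0.450)
  )
  effects <- data.frame(
    marker = c("B7-H4", "CK7", "CK20"),
    covariate = c("origin", "origin", "origin"),
    level = c("secondary", "secondary", "secondary"),
    offset = c(-0.7, -0.7, 0.6),
    stringsAsFactors = FALSE
  )
  generatorConfig(nPatients = 48, prevalence = prevalence,
                  # patient-level exact counts: 6 of 48 secondary origin
                  covariateFreqs = list(origin = c(primary = 42 / 48,
                                                   secondary = 6 / 48)),
                  effects = effects, tilCd8Coupling = 0.5)
}

.lookupPrevalence <- function(prev, marker, component) {
  p <- prev[[marker]]
  if (is.null(p)) return(0)
  if (length(p) == 1 && is.null(names(p))) return(as.numeric(p))
  if (component %in% names(p)) return(as.numeric(p[[component]]))
  if ("invasive" %in% names(p)) return(as.numeric(p[["invasive"]]))
  as.numeric(p[[1]])
}

# exact-count category allocation: largest-remainder rounding of the
# normalized frequencies, then a random permutation over patients
.allocateCategories <- function(freqs, n) {
  if (n == 0) return(character())
  raw <- freqs / sum(freqs) * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  sample(rep(names(freqs), times = k))
}

#' Generate a synthetic cohort
#'
#' Simulates a specimen-level cohort under `config`: patients receive
#' clinical covariates by exact-count allocation; a fixed number gain a
#' second resection; specimen components follow the patient's disease
#' extent; marker positivity is Bernoulli per (case, marker) with invasive
#' states coupled to in situ states at the configured copy probability and
#' prevalence offsets applied per covariate effects; positive components
#' draw a composite score from the marker's score distribution (duplicate
#' blocks share the positivity state but draw independently jittered
#' scores); components become unscorable (`NA`) at the configured rate; TIL
#' fields and a lognormal CD8 density are drawn per specimen.
#'
#' Identical `(config, seed)` yields an identical cohort. Randomness is
#' split into named per-stage substreams from the root seed, so the draws
#' of one stage do not perturb another.
#'
#' @param config A [GeneratorConfig].
#' @param seed Optional root seed overriding `config@seed`.
#' @return A validated [IHCCohort] (passes [validateCohort()]).
#' @export
#' @examples
#' cohort <- generateCohort(generatorConfig(nPatients = 6, seed = 7))
#' cohort
generateCohort <- function(config, seed = NULL) {
  methods::validObject(config)
  if (is.null(seed)) seed <- config@seed
  stageSeeds <- .withSeed(seed, sample.int(2^31 - 2, 8))
  n <- config@nPatients

  empty <- function() IHCCohort(
    matrix(numeric(), 10, 0, dimnames = list(markerPanel(), NULL)),
    matrix(numeric(), 10, 0, dimnames = list(markerPanel(), NULL)),
    .emptyCovariates())
  if (n == 0) return(empty())

  # stage 1: patient-level covariates
  cf <- config@covariateFreqs
  pat <- .withSeed(stageSeeds[1], data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = .allocateCategories(cf$sex, n),
    extent = .allocateCategories(cf$extent, n),
    origin = .allocateCategories(cf$origin, n),
    site = .allocateCategories(cf$site, n),
    treatment = .allocateCategories(cf$treatment, n),
    vital_status = .allocateCategories(cf$vital_status, n),
    age = pmin(92, pmax(39, round(stats::rnorm(n, 69, 12)))),
    stringsAsFactors = FALSE
  ))

  # stage 2: resections, components, dual blocks
  specimens <- .withSeed(stageSeeds[2], {
    nSecond <- round(config@secondResectionRate * n)
    second <- sample(pat$patient_id, nSecond)
    rows <- list()
    for (i in seq_len(n)) {
      res <- if (pat$patient_id[i] %in% second) c("a", "b") else "none"
      for (r in res) {
        comps <- switch(pat$extent[i],
          in_situ = "in_situ",
          invasive = if (stats::rbinom(1, 1, config@bothComponentRate) == 1)
            c("in_situ", "invasive") else "invasive",
          metastatic = "metastatic")
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pat$patient_id[i], resection_label = r,
          components = I(list(comps)), stringsAsFactors = FALSE)
      }
    }
    sp <- do.call(rbind, rows)
    nDual <- round(config@dualBlockRate * nrow(sp))
    sp$nBlocks <- 1L
    if (nDual > 0)
      sp$nBlocks[sample.int(nrow(sp), nDual)] <- 2L
    sp
  })
  nSpec <- nrow(specimens)

  # stage 3: latent positivity per (specimen, marker, component)
  markers <- markerPanel()
  kappa <- config@componentConcordance
  posState <- .withSeed(stageSeeds[3], {
    lapply(seq_len(nSpec), function(s) {
      pi <- match(specimens$patient_id[s], pat$patient_id)
      sapply(markers, function(m) {
        adj <- 0
        if (nrow(config@effects)) {
          eff <- config@effects
          hit <- eff$marker == m &
            mapply(function(cv, lv) pat[[cv]][pi] == lv,
                   eff$covariate, eff$level)
          adj <- sum(eff$offset[hit])
        }
        pIS <- min(1, max(0, .lookupPrevalence(config@prevalence, m, "in_situ") + adj))
        pIV <- min(1, max(0, .lookupPrevalence(config@prevalence, m, "invasive") + adj))
        pMT <- min(1, max(0, .lookupPrevalence(config@prevalence, m, "metastatic") + adj))
        zIS <- stats::rbinom(1, 1, pIS)
        zIV <- if (stats::rbinom(1, 1, kappa) == 1) zIS else stats::rbinom(1, 1, pIV)
        zMT <- stats::rbinom(1, 1, pMT)
        c(in_situ = zIS, invasive = zIV, metastatic = zMT)
      })
    })
  })

  # stage 4: NA mask per (specimen, component, marker)
  naMask <- .withSeed(stageSeeds[4], {
    lapply(seq_len(nSpec), function(s)
      sapply(markers, function(m)
        stats::rbinom(3, 1, config@naRate) == 1))
  })

  # stage 5: composite scores per block
  drawScore <- function(m) {
    sd <- config@scoreDist[[m]]
    if (is.null(sd)) sd <- .DEFAULT_SCORE_DIST
    as.numeric(names(sd))[sample.int(length(sd), 1, prob = sd)]
  }

  build <- .withSeed(stageSeeds[5], {
    cols <- list(); cov <- list()
    for (s in seq_len(nSpec)) {
      pi <- match(specimens$patient_id[s], pat$patient_id)
      comps <- specimens$components[[s]]
      for (comp in comps) {
        ci <- match(comp, c("in_situ", "invasive", "metastatic"))
        for (blk in seq_len(specimens$nBlocks[s])) {
          pctv <- intv <- numeric(10)
          for (mi in seq_along(markers)) {
            m <- markers[mi]
            if (naMask[[s]][ci, m]) { pctv[mi] <- intv[mi] <- NA; next }
            if (posState[[s]][comp, m] == 1) {
              f <- .SCORE_FACTORS[[as.character(drawScore(m))]]
              pctv[mi] <- f[1]; intv[mi] <- f[2]
            } # else stays 0,0
          }
          cols[[length(cols) + 1]] <- list(pct = pctv, int = intv)
          cov[[length(cov) + 1]] <- data.frame(
            patient_id = specimens$patient_id[s],
            resection_label = specimens$resection_label[s],
            block_id = paste0("B", blk), component = comp,
            specimen = s, stringsAsFactors = FALSE)
        }
      }
    }
    list(cols = cols, cov = do.call(rbind, cov))
  })

  # stage 6: TIL fields and CD8 density per specimen
  tilSpec <- .withSeed(stageSeeds[6], {
    tb <- sample(0:4, nSpec, replace = TRUE, prob = config@tilB7h3Dist)
    data.frame(
      til_b7h3 = tb,
      til_b7h4 = stats::rbinom(nSpec, 1, config@tilRates[["til_b7h4"]]),
      til_pdl1 = stats::rbinom(nSpec, 1, config@tilRates[["til_pdl1"]]),
      til_pdl2 = stats::rbinom(nSpec, 1, config@tilRates[["til_pdl2"]]),
      cd8_density = round(stats::rlnorm(
        nSpec, config@cd8Meanlog + config@tilCd8Coupling * tb,
        config@cd8Sdlog), 2)
    )
  })

  cd <- build$cov
  pi <- match(cd$patient_id, pat$patient_id)
  cd <- cbind(
    cd[c("patient_id", "resection_label", "block_id", "component")],
    pat[pi, c("sex", "age", "extent", "origin", "site", "treatment",
              "vital_status")],
    tilSpec[cd$specimen, c("cd8_density", "til_b7h3", "til_b7h4",
                           "til_pdl1", "til_pdl2")]
  )
  cd <- cd[, .COVARIATE_COLS]
  rownames(cd) <- NULL
  pct <- vapply(build$cols, `[[`, numeric(10), "pct")
  int <- vapply(build$cols, `[[`, numeric(10), "int")
  rownames(pct) <- rownames(int) <- markers
  IHCCohort(pct, int, cd)
}
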