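# Fixture builders used across test files. Everything is constructed in
# code; no data files.

# deterministic (pct, int) factorization for each attainable composite
.factorize_score <- function(s) {
  map <- list(`0` = c(0, 0), `1` = c(1, 1), `2` = c(2, 1), `3` = c(3, 1),
              `4` = c(4, 1), `6` = c(3, 2), `8` = c(4, 2), `9` = c(3, 3),
              `12` = c(4, 3))
  map[[as.character(s)]]
}

# build a cohort from a markers x records score matrix (attainable values or
# NA) plus per-record covariates
make_cohort <- function(score, patient_id, component,
                        resection_label = rep("none", ncol(score)),
                        block_id = rep("B1", ncol(score)),
                        origin = rep("primary", ncol(score)),
                        sex = rep("female", ncol(score)),
                        site = rep("vulvar", ncol(score)),
                        vital_status = rep("unknown", ncol(score)),
                        cd8_density = rep(100, ncol(score)),
                        til_b7h3 = rep(1, ncol(score)),
                        til_pdl1 = rep(1, ncol(score)),
                        til_pdl2 = rep(0, ncol(score))) {
  stopifnot(nrow(score) == 10)
  rownames(score) <- markerPanel()
  pct <- int <- score
  for (j in seq_len(ncol(score))) for (i in 1:10) {
    if (is.na(score[i, j])) next
    f <- .factorize_score(score[i, j])
    pct[i, j] <- f[1]; int[i, j] <- f[2]
  }
  cd <- data.frame(
    patient_id = patient_id, resection_label = resection_label,
    block_id = block_id, component = component, sex = sex, age = 69,
    extent = component, origin = origin, site = site, treatment = "none",
    vital_status = vital_status, cd8_density = cd8_density,
    til_b7h3 = til_b7h3, til_b7h4 = 0, til_pdl1 = til_pdl1,
    til_pdl2 = til_pdl2, stringsAsFactors = FALSE
  )
  IHCCohort(pct, int, cd)
}

# cohort where every case carries both components with given score matrices
make_paired_cohort <- function(scoreIS, scoreIV, ...) {
  n <- ncol(scoreIS)
  ids <- sprintf("C%02d", seq_len(n))
  sc <- cbind(scoreIS, scoreIV)
  make_cohort(sc, patient_id = c(ids, ids),
              component = rep(c("in_situ", "invasive"), each = n), ...)
}

# small null-screen generator config (one record per patient, balanced sex)
null_screen_config <- function(n = 40, prevalence = 0.5) {
  generatorConfig(
    nPatients = n,
    prevalence = stats::setNames(as.list(rep(prevalence, 10)), markerPanel()),
    covariateFreqs = list(sex = c(female = 0.5, male = 0.5),
                          extent = c(in_situ = 1),
                          origin = c(primary = 1),
                          vital_status = c(unknown = 1)),
    naRate = 0, dualBlockRate = 0, secondResectionRate = 0
  )
}
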