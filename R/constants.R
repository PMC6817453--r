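# Panel and category vocabularies shared across the package.

# display name -> CSV column token
.MARKER_TOKENS <- c(
  "B7-H3"    = "b7h3",
  "B7-H4"    = "b7h4",
  "PD-L1"    = "pdl1",
  "PD-L2"    = "pdl2",
  "MAGE-A"   = "magea",
  "NY-ESO-1" = "nyeso1",
  "B2M"      = "b2m",
  "MHC-I"    = "mhc1",
  "CK7"      = "ck7",
  "CK20"     = "ck20"
)

.COMPONENTS <- c("in_situ", "invasive", "metastatic")
.RESECTIONS <- c("none", "a", "b")
.SEX        <- c("female", "male")
.EXTENT     <- c("in_situ", "invasive", "metastatic")
.ORIGIN     <- c("primary", "secondary")
.SITE       <- c("vulvar", "penile_scrotal", "perianal", "perineum", "other")
.VITAL      <- c("alive", "death_from_disease", "death_unrelated", "unknown")

# covariate columns of the specimen-level schema, in CSV order
.COVARIATE_COLS <- c(
  "patient_id", "resection_label", "block_id", "component",
  "sex", "age", "extent", "origin", "site", "treatment", "vital_status",
  "cd8_density", "til_b7h3", "til_b7h4", "til_pdl1", "til_pdl2"
)

#' Tumor marker panel
#'
#' The ten tumor-cell markers assessed per specimen component, in canonical
#' panel order: B7 family (B7-H3, B7-H4, PD-L1, PD-L2), cancer/testis
#' antigens (MAGE-A, NY-ESO-1), antigen-presenting machinery (B2M, MHC-I)
#' and cytokeratins (CK7, CK20).
#'
#' @return Character vector of marker display names.
#' @export
#' @examples
#' markerPanel()
markerPanel <- function() names(.MARKER_TOKENS)

#' Attainable composite IHC scores before block averaging
#'
#' The composite score is the product of the percent-positive category (0-4)
#' and the staining intensity (0-3); before dual-block averaging it can only
#' take the values in the 5 x 4 product table.
#'
#' @return Sorted numeric vector of attainable products.
#' @export
#' @examples
#' attainableCompositeScores()  # 0 1 2 3 4 6 8 9 12
attainableCompositeScores <- function() {
  sort(unique(as.vector(outer(0:4, 0:3))))
}

# run code with a locally seeded RNG, restoring the caller's stream
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}
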