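# Complete-linkage agglomerative clustering on Manhattan distances with the
# exclude-and-rescale missing-value convention, plus cohort-level helpers.

#' Manhattan distance with missing-value rescaling
#'
#' Coordinates missing in either vector are excluded and the partial sum is
#' rescaled by `p / np` (total coordinates over complete pairs), the
#' documented behavior of the standard R distance routine. With no missing
#' values this is the plain Manhattan distance.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Nonnegative distance; errors if no coordinate pair is complete.
#' @export
#' @examples
#' manhattanDistanceNA(c(1, NA, 3, 5), c(2, 7, NA, 5))  # 2
manhattanDistanceNA <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  np <- sum(keep)
  if (np == 0) stop("no complete coordinate pairs", call. = FALSE)
  (length(x) / np) * sum(abs(x[keep] - y[keep]))
}

# full pairwise distance matrix over the rows of m
.rowDistances <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2) return(D)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- manhattanDistanceNA(m[i, ], m[j, ])
  D
}

#' Dendrogram: an agglomerative merge tree
#'
#' Holds the merge sequence in `hclust` coding (`merge`: negative entries
#' are leaves, positive entries earlier merges), the merge `height`s, the
#' leaf `order` and the leaf `labels`. Convert with
#' `as.hclust(dendrogram)` for plotting or [stats::cutree()].
#'
#' @slot merge integer matrix, (n-1) x 2.
#' @slot height numeric vector of merge heights (non-decreasing under
#'   complete linkage).
#' @slot order integer leaf permutation.
#' @slot labels character leaf labels.
#' @aliases Dendrogram-class
#' @export
setClass("Dendrogram", representation(
  merge = "matrix", height = "numeric", order = "integer",
  labels = "character"
))

setValidity("Dendrogram", function(object) {
  n <- length(object@labels)
  if (n >= 1 && nrow(object@merge) != n - 1)
    return("a dendrogram over n leaves needs n-1 merges")
  if (nrow(object@merge) != length(object@height))
    return("merge/height length mismatch")
  TRUE
})

setMethod("show", "Dendrogram", function(object) {
  cat("Dendrogram over", length(object@labels), "leaves;",
      "height range [", format(min(object@height)), ",",
      format(max(object@height)), "]\n")
})

#' @export
as.hclust.Dendrogram <- function(x, ...) {
  structure(
    list(merge = x@merge, height = x@height, order = x@order,
         labels = x@labels, method = "complete",
         dist.method = "manhattan", call = match.call()),
    class = "hclust"
  )
}

# leaf order by depth-first traversal of the merge tree
.leafOrder <- function(merge) {
  n <- nrow(merge) + 1
  if (n == 1) return(1L)
  rec <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    left <- if (merge[k, 1] < 0) -merge[k, 1] else rec[[merge[k, 1]]]
    right <- if (merge[k, 2] < 0) -merge[k, 2] else rec[[merge[k, 2]]]
    rec[[k]] <- c(left, right)
  }
  as.integer(rec[[nrow(merge)]])
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerates the items of a pairwise distance table, at each step merging
#' the pair of clusters with the smallest inter-cluster distance, where the
#' inter-cluster distance is the *maximum* pairwise item distance
#' (Lance-Williams update `d(k, i+j) = max(d(k,i), d(k,j))`). Ties are
#' broken deterministically in favor of the lexicographically smallest pair
#' of cluster indices (clusters indexed by creation order: singletons first,
#' then merges).
#'
#' @param distances A `dist` object or symmetric numeric matrix with zero
#'   diagonal.
#' @return A [Dendrogram].
#' @export
#' @examples
#' d <- .rowDistances(matrix(c(0, 1, 10), ncol = 1,
#'                    dimnames = list(c("a", "b", "c"), NULL)))
#' completeLinkage(d)@height  # 1 10
completeLinkage <- function(distances) {
  D <- as.matrix(distances)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) ||
      any(abs(diag(D)) > 1e-8))
    stop("distance table must be symmetric with zero diagonal", call. = FALSE)
  n <- nrow(D)
  if (n < 2) stop("need at least two items", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  code <- -(seq_len(n))        # hclust code of each active cluster
  created <- seq_len(n)        # creation index (tie-break key)
  active <- rep(TRUE, n)
  mergeM <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  W <- D

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL; bestD <- Inf
    for (ii in seq_along(idx)) {
      if (ii == length(idx)) break
      for (jj in (ii + 1):length(idx)) {
        i <- idx[ii]; j <- idx[jj]
        key <- sort(c(created[i], created[j]))
        d <- W[i, j]
        if (d < bestD - 1e-12 ||
            (abs(d - bestD) <= 1e-12 && !is.null(best) &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, key = key); bestD <- d
        }
      }
    }
    i <- best$i; j <- best$j
    ci <- code[i]; cj <- code[j]
    # hclust row convention: singletons (negative) before merges, ascending
    pair <- c(ci, cj)
    pair <- pair[order(pair >= 0, abs(pair))]
    mergeM[step, ] <- pair
    heights[step] <- bestD
    # merged cluster replaces position i
    W[i, ] <- pmax(W[i, ], W[j, ])
    W[, i] <- W[i, ]
    W[i, i] <- 0
    active[j] <- FALSE
    code[i] <- step
    created[i] <- n + step
  }
  new("Dendrogram", merge = mergeM, height = heights,
      order = .leafOrder(mergeM), labels = labels)
}

#' Composite-score matrix for one tumor component
#'
#' @param cohort An [IHCCohort]; duplicate blocks are averaged first.
#' @param component Tumor component.
#' @return Numeric matrix, markers x cases, with case labels
#'   (patient id plus resection suffix) as column names.
#' @export
scoreMatrix <- function(cohort, component) {
  cohort <- collapseBlocks(cohort)
  sel <- .selectComponent(cohort, component)
  if (length(sel) == 0) stop("no cases with component ", component, call. = FALSE)
  cd <- SummarizedExperiment::colData(cohort)[sel, , drop = FALSE]
  m <- scores(cohort)[, sel, drop = FALSE]
  colnames(m) <- paste0(cd$patient_id,
                        ifelse(cd$resection_label == "none", "",
                               as.character(cd$resection_label)))
  m
}

#' Per-case covariate annotation tracks for one component
#'
#' Display-only annotations (they never enter any distance computation):
#' CD8 density, sex, site, origin, extent and treatment per case.
#'
#' @inheritParams scoreMatrix
#' @return `data.frame`, one row per case, rownames matching
#'   [scoreMatrix()] columns.
#' @export
caseAnnotations <- function(cohort, component) {
  cohort <- collapseBlocks(cohort)
  sel <- .selectComponent(cohort, component)
  cd <- SummarizedExperiment::colData(cohort)[sel, , drop = FALSE]
  out <- data.frame(
    cd8_density = as.numeric(cd$cd8_density), sex = cd$sex, site = cd$site,
    origin = cd$origin, extent = cd$extent, treatment = cd$treatment,
    stringsAsFactors = FALSE
  )
  rownames(out) <- paste0(cd$patient_id,
                          ifelse(cd$resection_label == "none", "",
                                 as.character(cd$resection_label)))
  out
}

#' CohortClustering: clustering result for one component
#'
#' @slot matrix ordered score matrix (markers x cases, leaf orders applied).
#' @slot markerDendrogram,caseDendrogram [Dendrogram]s over rows/columns.
#' @slot annotations per-case covariate tracks (display only).
#' @aliases CohortClustering-class
#' @export
setClass("CohortClustering", representation(
  matrix = "matrix", markerDendrogram = "Dendrogram",
  caseDendrogram = "Dendrogram", annotations = "data.frame"
))

setMethod("show", "CohortClustering", function(object) {
  cat("CohortClustering:", nrow(object@matrix), "markers x",
      ncol(object@matrix), "cases\n")
})

#' Cluster the cases and markers of one tumor component
#'
#' Markers (rows) and cases (columns) of the raw composite-score matrix are
#' clustered independently with complete linkage on the
#' missing-value-rescaled Manhattan distance ([manhattanDistanceNA()]).
#' Scores enter unscaled. Fully missing cases/markers are removed with a
#' warning before clustering. Covariate annotations are attached for
#' display and never enter the distances.
#'
#' @inheritParams scoreMatrix
#' @return A [CohortClustering].
#' @export
clusterCohort <- function(cohort, component) {
  m <- scoreMatrix(cohort, component)
  ann <- caseAnnotations(cohort, component)
  allNA <- colSums(!is.na(m)) == 0
  if (any(allNA)) {
    warning("removing fully missing case(s): ",
            paste(colnames(m)[allNA], collapse = ", "), call. = FALSE)
    m <- m[, !allNA, drop = FALSE]
    ann <- ann[!allNA, , drop = FALSE]
  }
  rowNA <- rowSums(!is.na(m)) == 0
  if (any(rowNA)) {
    warning("removing fully missing marker(s): ",
            paste(rownames(m)[rowNA], collapse = ", "), call. = FALSE)
    m <- m[!rowNA, , drop = FALSE]
  }
  dRow <- .rowDistances(m)
  dCol <- .rowDistances(t(m))
  denRow <- completeLinkage(dRow)
  denCol <- completeLinkage(dCol)
  ordered <- m[denRow@order, denCol@order, drop = FALSE]
  new("CohortClustering", matrix = ordered,
      markerDendrogram = denRow, caseDendrogram = denCol,
      annotations = ann[denCol@order, , drop = FALSE])
}

# plain-list view of a Dendrogram for JSON export
.dendrogramToList <- function(d) {
  list(labels = d@labels, order = d@order,
       merges = lapply(seq_along(d@height), function(k)
         list(a = d@merge[k, 1], b = d@merge[k, 2], height = d@height[k])))
}
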