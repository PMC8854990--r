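#' Number of subjects in a cohort
#' @param x a [Cohort-class]
#' @return integer
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Number of ROIs (graph nodes)
#' @param x a [Cohort-class] or [SparseGraph-class]
#' @return integer
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' Subject diagnosis labels (0/1)
#' @param x a [Cohort-class]
#' @return integer vector
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))

#' Acquisition-site labels
#' @param x a [Cohort-class]
#' @return character vector
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' ROI centroid coordinates
#' @param x a [Cohort-class]
#' @return N x 3 numeric matrix
#' @export
setGeneric("roiCoords", function(x) standardGeneric("roiCoords"))

#' Planted ground-truth informative edges
#' @param x a [Cohort-class]
#' @return integer matrix with columns i, j (0 rows if unknown)
#' @export
setGeneric("truthEdges", function(x) standardGeneric("truthEdges"))

#' Graph adjacency matrix
#' @param x a [SparseGraph-class]
#' @return N x N numeric matrix
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "Cohort", function(x) length(x@series))

#' @rdname nRois
#' @export
setMethod("nRois", "Cohort", function(x) length(x@roiIds))

#' @rdname nRois
#' @export
setMethod("nRois", "SparseGraph", function(x) nrow(x@adjacency))

#' @rdname subjectLabels
#' @export
setMethod("subjectLabels", "Cohort", function(x) x@labels)

#' @rdname siteLabels
#' @export
setMethod("siteLabels", "Cohort", function(x) x@sites)

#' @rdname roiCoords
#' @export
setMethod("roiCoords", "Cohort", function(x) x@coords)

#' @rdname truthEdges
#' @export
setMethod("truthEdges", "Cohort", function(x) x@truthEdges)

#' @rdname adjacency
#' @export
setMethod("adjacency", "SparseGraph", function(x) x@adjacency)

setMethod("show", "Cohort", function(object) {
  n <- nSubjects(object)
  cat(sprintf("Cohort: %d subjects, %d ROIs, %d sites\n",
              n, nRois(object), length(unique(object@sites))))
  cat(sprintf("  labels: %d class-0 / %d class-1\n",
              sum(object@labels == 0L), sum(object@labels == 1L)))
  if (n && !is.null(object@series[[1]]))
    cat(sprintf("  time points: %d\n", nrow(object@series[[1]])))
  else cat("  connectivity-only cohort (no raw series)\n")
  if (nrow(object@truthEdges))
    cat(sprintf("  planted informative edges: %d\n", nrow(object@truthEdges)))
  invisible(NULL)
})

setMethod("show", "SparseGraph", function(object) {
  A <- object@adjacency
  cat(sprintf("SparseGraph (%s): %d nodes, %d edges, k = %d\n",
              object@kind, nrow(A), sum(A[upper.tri(A)] > 0), object@k))
  invisible(NULL)
})

setMethod("show", "FeatureSelection", function(object) {
  cat(sprintf("FeatureSelection: %d ROIs, M = %d static + J = %d dynamic per ROI (seed %d)\n",
              object@nRois, object@M, object@J, object@seed))
  invisible(NULL)
})

setMethod("show", "IDGCNModel", function(object) {
  cat(sprintf("IDGCNModel: %d invertible blocks, K = %d, N = %d ROIs, F = %d features, %d sites\n",
              length(object@blocks), object@K, object@nRois, object@featureDim,
              object@nSites))
  cat(sprintf("  %s\n", if (object@trained) "trained" else "untrained (initial weights)"))
  invisible(NULL)
})

setMethod("show", "ImportanceReport", function(object) {
  cat(sprintf("ImportanceReport: %d scored edges, top %.0f%% listed (%d edges)%s\n",
              sum(object@edgeScores[upper.tri(object@edgeScores)] > 0),
              100 * object@topFraction, nrow(object@topEdges),
              if (length(object@nodeScores)) sprintf(", %d node lesion scores",
                                                     length(object@nodeScores)) else ""))
  invisible(NULL)
})
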