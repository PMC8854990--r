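#' @import methods
NULL

#' Cohort of subjects with ROI time series and metadata
#'
#' Container for a study cohort: one region-of-interest (ROI) time-series
#' matrix per subject (rows = time points, columns = ROIs), a binary
#' diagnosis label and an acquisition-site label per subject, and the ROI
#' centroid coordinates shared by all subjects. Cohorts produced by
#' [simulateCohort()] additionally carry the planted ground-truth edge set
#' so that recovery can be tested. Precomputed connectivity-only cohorts
#' (no raw series) are supported: `series` entries may be `NULL` when
#' `connectivity` entries are present.
#'
#' @slot series list of T x N numeric matrices (or NULLs when only
#'   connectivity is available), one per subject.
#' @slot connectivity list of N x N correlation matrices or NULLs; filled
#'   lazily by [cohortConnectivity()].
#' @slot labels integer vector of 0/1 diagnosis labels.
#' @slot sites character vector of acquisition-site labels.
#' @slot coords N x 3 numeric matrix of ROI centroids (mm).
#' @slot roiIds character vector of ROI identifiers.
#' @slot truthEdges integer matrix with columns `i`, `j` of planted
#'   informative edges (0 rows when unknown/real data).
#' @slot spec list of generator settings (empty for read-in cohorts).
#'
#' @seealso [simulateCohort()], [readCohort()], [writeCohort()]
#' @export
setClass("Cohort", representation(
  series = "list",
  connectivity = "list",
  labels = "integer",
  sites = "character",
  coords = "matrix",
  roiIds = "character",
  truthEdges = "matrix",
  spec = "list"
))

setValidity("Cohort", function(object) {
  n <- length(object@series)
  msgs <- character()
  if (length(object@labels) != n) msgs <- c(msgs, "labels length != number of subjects")
  if (length(object@sites) != n) msgs <- c(msgs, "sites length != number of subjects")
  if (!all(object@labels %in% c(0L, 1L))) msgs <- c(msgs, "labels must be 0 or 1")
  if (ncol(object@coords) != 3) msgs <- c(msgs, "coords must have 3 columns")
  if (nrow(object@coords) != length(object@roiIds))
    msgs <- c(msgs, "coords rows != number of ROI ids")
  if (length(object@connectivity) && length(object@connectivity) != n)
    msgs <- c(msgs, "connectivity length != number of subjects")
  N <- length(object@roiIds)
  for (s in seq_len(n)) {
    ts <- object@series[[s]]
    if (is.null(ts)) next
    if (ncol(ts) != N) {
      msgs <- c(msgs, sprintf("subject %d has %d ROIs, cohort has %d", s, ncol(ts), N))
      break
    }
    if (nrow(ts) < 2) { msgs <- c(msgs, sprintf("subject %d has < 2 time points", s)); break }
  }
  if (nrow(object@truthEdges) && ncol(object@truthEdges) != 2)
    msgs <- c(msgs, "truthEdges must have 2 columns")
  if (length(msgs)) msgs else TRUE
})

#' Sparse k-nearest graph over ROIs
#'
#' Symmetric non-negative adjacency with zero diagonal, obtained by keeping
#' each node's k strongest functional neighbours (largest absolute
#' correlation) or k spatially nearest neighbours, symmetrised by union so
#' every node retains at least k neighbours.
#'
#' @slot adjacency N x N non-negative symmetric weight matrix, zero diagonal.
#' @slot kind `"functional"` or `"spatial"`.
#' @slot k integer, neighbours requested per node.
#' @seealso [knnFunctionalGraph()], [knnSpatialGraph()]
#' @export
setClass("SparseGraph", representation(
  adjacency = "matrix",
  kind = "character",
  k = "integer"
))

setValidity("SparseGraph", function(object) {
  A <- object@adjacency
  msgs <- character()
  if (nrow(A) != ncol(A)) msgs <- c(msgs, "adjacency must be square")
  else {
    if (max(abs(A - t(A))) > 1e-10) msgs <- c(msgs, "adjacency must be symmetric")
    if (any(A < 0)) msgs <- c(msgs, "adjacency weights must be non-negative")
    if (any(diag(A) != 0)) msgs <- c(msgs, "adjacency diagonal must be zero")
  }
  if (!object@kind %in% c("functional", "spatial"))
    msgs <- c(msgs, "kind must be 'functional' or 'spatial'")
  if (length(msgs)) msgs else TRUE
})

#' Normalized and rescaled graph Laplacian
#'
#' Holds L = I - D^{-1/2} A D^{-1/2} (spectrum in [0, 2]) and its rescaled
#' form Ltilde = (2/lambdaMax) L - I (spectrum in [-1, 1]) used by the
#' Chebyshev filters.
#'
#' @slot L normalized Laplacian matrix.
#' @slot Ltilde rescaled Laplacian.
#' @slot lambdaMax largest eigenvalue of L used for the rescaling.
#' @seealso [normalizedLaplacian()], [scaledLaplacian()]
#' @export
setClass("ScaledLaplacian", representation(
  L = "matrix",
  Ltilde = "matrix",
  lambdaMax = "numeric"
))

setValidity("ScaledLaplacian", function(object) {
  msgs <- character()
  if (max(abs(object@L - t(object@L))) > 1e-8) msgs <- c(msgs, "L must be symmetric")
  if (length(object@Ltilde) && max(abs(object@Ltilde - t(object@Ltilde))) > 1e-8)
    msgs <- c(msgs, "Ltilde must be symmetric")
  if (length(object@lambdaMax) && object@lambdaMax <= 0)
    msgs <- c(msgs, "lambdaMax must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Per-ROI feature selection from random-forest screening
#'
#' For every ROI, the indices (neighbour ROI numbers) of the M static
#' correlation features and J dynamic-variability features retained by the
#' per-ROI random-forest importance ranking. The self-index is never
#' selected.
#'
#' @slot staticIdx list (length N) of integer vectors, each of length M.
#' @slot dynamicIdx list (length N) of integer vectors, each of length J
#'   (J = 0 gives empty vectors).
#' @slot M integer, static features kept per ROI.
#' @slot J integer, dynamic features kept per ROI.
#' @slot nRois integer.
#' @slot seed integer seed that fixed the forest randomness.
#' @seealso [fitScreening()], [applyScreening()]
#' @export
setClass("FeatureSelection", representation(
  staticIdx = "list",
  dynamicIdx = "list",
  M = "integer",
  J = "integer",
  nRois = "integer",
  seed = "integer"
))

setValidity("FeatureSelection", function(object) {
  msgs <- character()
  N <- object@nRois
  if (length(object@staticIdx) != N) msgs <- c(msgs, "staticIdx length != nRois")
  if (length(object@dynamicIdx) != N) msgs <- c(msgs, "dynamicIdx length != nRois")
  for (r in seq_len(N)) {
    si <- object@staticIdx[[r]]
    di <- object@dynamicIdx[[r]]
    if (length(si) != object@M) { msgs <- c(msgs, "static selection size != M"); break }
    if (length(di) != object@J) { msgs <- c(msgs, "dynamic selection size != J"); break }
    if (anyDuplicated(si) || anyDuplicated(di)) { msgs <- c(msgs, "duplicate selected index"); break }
    if (r %in% si || r %in% di) { msgs <- c(msgs, "self-index selected"); break }
    if (length(si) && (min(si) < 1 || max(si) > N)) { msgs <- c(msgs, "selected index out of range"); break }
  }
  if (length(msgs)) msgs else TRUE
})

#' Trained (or initialised) invertible dynamic GCN model
#'
#' Parameters of the full network: an ordered list of additive invertible
#' blocks, each coupling a spatial-graph Chebyshev GCN (phi) and a
#' functional-graph Chebyshev GCN (omega), followed by a fully connected
#' softmax layer over the flattened block outputs plus the site one-hot
#' covariate.
#'
#' @slot blocks list of block parameter lists, each `list(phi = list(W=...),
#'   omega = list(W=...))` with K weight matrices of size F x F per module.
#' @slot fcW 2 x (2*N*F + nSites) fully-connected weight matrix.
#' @slot fcB length-2 bias vector.
#' @slot K integer Chebyshev order.
#' @slot nRois integer N.
#' @slot featureDim integer F = M + J.
#' @slot nSites integer number of site levels.
#' @slot siteLevels character levels used for the one-hot encoding.
#' @slot selection the [FeatureSelection-class] used to build inputs.
#' @slot config list of training settings actually used.
#' @slot trained logical.
#' @export
setClass("IDGCNModel", representation(
  blocks = "list",
  fcW = "matrix",
  fcB = "numeric",
  K = "integer",
  nRois = "integer",
  featureDim = "integer",
  nSites = "integer",
  siteLevels = "character",
  selection = "FeatureSelection",
  config = "list",
  trained = "logical"
))

setValidity("IDGCNModel", function(object) {
  msgs <- character()
  D <- 2L * object@nRois * object@featureDim + object@nSites
  if (ncol(object@fcW) != D)
    msgs <- c(msgs, sprintf("fc input dim %d != 2*N*F + nSites = %d", ncol(object@fcW), D))
  if (nrow(object@fcW) != 2) msgs <- c(msgs, "fcW must have 2 rows")
  if (length(object@fcB) != 2) msgs <- c(msgs, "fcB must have length 2")
  for (b in object@blocks) {
    for (mod in c("phi", "omega")) {
      Ws <- b[[mod]]$W
      if (length(Ws) != object@K) { msgs <- c(msgs, "block weight stack length != K"); break }
      for (W in Ws) if (!all(dim(W) == object@featureDim)) {
        msgs <- c(msgs, "block weights must be F x F"); break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Edge- and node-importance report
#'
#' Interpretation output: reconstruction-based edge scores (symmetric,
#' non-negative, zero diagonal), the ranked top fraction of edges, and
#' (optionally) per-node lesion scores (classification-accuracy drop when
#' the node is removed).
#'
#' @slot edgeScores N x N symmetric non-negative score matrix.
#' @slot topEdges data.frame with columns roi_i, roi_j, score, sorted
#'   descending by score.
#' @slot nodeScores numeric length-N vector of accuracy drops (may be
#'   length 0 when lesion analysis was not run).
#' @slot topFraction numeric fraction of scored edges retained.
#' @seealso [edgeImportance()], [lesionImportance()]
#' @export
setClass("ImportanceReport", representation(
  edgeScores = "matrix",
  topEdges = "data.frame",
  nodeScores = "numeric",
  topFraction = "numeric"
))

setValidity("ImportanceReport", function(object) {
  msgs <- character()
  E <- object@edgeScores
  if (length(E)) {
    if (max(abs(E - t(E))) > 1e-9) msgs <- c(msgs, "edge scores must be symmetric")
    if (any(E < 0)) msgs <- c(msgs, "edge scores must be non-negative")
    if (any(diag(E) != 0)) msgs <- c(msgs, "edge score diagonal must be zero")
  }
  if (nrow(object@topEdges) > 1 && is.unsorted(rev(object@topEdges$score)))
    msgs <- c(msgs, "topEdges must be sorted descending")
  if (length(msgs)) msgs else TRUE
})
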