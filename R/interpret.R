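#' Reconstruction-based edge importance
#'
#' Maps the trained classifier's evidence back to connectivity space using
#' the network's invertibility: (1) each pre-classifier output unit is
#' scored by its class-discriminative contribution — the absolute
#' difference of its two fully-connected weight rows times its mean
#' absolute activation over the evaluated subjects (the weight difference
#' alone is scale-confounded: units with tiny activations carry large
#' compensating weights); (2) only the top `topFraction` of
#' units are kept, the rest are zeroed; (3) the masked output is pulled
#' back through the exact inverse of the block stack; (4) absolute
#' reconstructed magnitudes are averaged over subjects per (ROI, selected
#' feature) slot; (5) slot scores are scattered onto connectivity edges via
#' the feature-selection mapping and symmetrised by max. With
#' `topFraction = 1` the reconstruction returns the inputs exactly, so the
#' importance signal comes entirely from the masking.
#'
#' @param model a trained [IDGCNModel-class].
#' @param prep the `PreparedCohort` providing subjects and graph bases.
#' @param idx subjects to average over (default: all).
#' @param topFraction fraction of output units kept (default 0.10).
#' @return an [ImportanceReport-class] (edge part; `nodeScores` empty).
#' @export
edgeImportance <- function(model, prep, idx = NULL, topFraction = 0.10) {
  stopifnot(methods::is(model, "IDGCNModel"), topFraction > 0, topFraction <= 1)
  if (all(model@fcW == 0) && all(model@fcB == 0))
    stop("no discriminative weights: the fully connected layer is untrained")
  if (is.null(idx)) idx <- seq_len(prep$n)
  N <- model@nRois; F <- model@featureDim
  nUnits <- 2L * N * F
  sel <- model@selection
  feats <- .screenedFeatures(prep, sel, idx)
  units <- vapply(seq_along(idx), function(i) {
    s <- idx[i]
    out <- stackForward(feats[[i]], model@blocks,
                        prep$spatialBases[[s]], prep$functionalBases[[s]])
    c(as.vector(out$z1), as.vector(out$z2))
  }, numeric(nUnits))
  wdiff <- abs(model@fcW[1, seq_len(nUnits)] - model@fcW[2, seq_len(nUnits)])
  unitScore <- wdiff * rowMeans(abs(units))
  nKeep <- ceiling(topFraction * nUnits)
  keep <- order(unitScore, decreasing = TRUE)[seq_len(nKeep)]
  mask <- logical(nUnits); mask[keep] <- TRUE

  slotScore <- matrix(0, N, F)
  for (i in seq_along(idx)) {
    s <- idx[i]
    u <- units[, i]
    u[!mask] <- 0
    z1 <- matrix(u[seq_len(N * F)], N, F)
    z2 <- matrix(u[N * F + seq_len(N * F)], N, F)
    rec <- stackInverse(z1, z2, model@blocks,
                        prep$spatialBases[[s]], prep$functionalBases[[s]])
    slotScore <- slotScore + 0.5 * (abs(rec$x1) + abs(rec$x2))
  }
  slotScore <- slotScore / length(idx)

  # scatter slot scores to directed edges via the selection, then max-symmetrise
  S <- matrix(0, N, N)
  for (r in seq_len(N)) {
    for (m in seq_len(sel@M)) {
      j <- sel@staticIdx[[r]][m]
      S[r, j] <- max(S[r, j], slotScore[r, m])
    }
    if (sel@J > 0) for (m in seq_len(sel@J)) {
      j <- sel@dynamicIdx[[r]][m]
      S[r, j] <- max(S[r, j], slotScore[r, sel@M + m])
    }
  }
  scored <- (S > 0) | t(S > 0)
  E <- pmax(S, t(S))
  diag(E) <- 0

  up <- which(upper.tri(E) & scored, arr.ind = TRUE)
  nScored <- nrow(up)
  ord <- order(E[up], decreasing = TRUE)
  nTop <- ceiling(topFraction * nScored)
  topIdx <- up[ord[seq_len(nTop)], , drop = FALSE]
  topEdges <- data.frame(roi_i = topIdx[, 1], roi_j = topIdx[, 2],
                         score = E[topIdx])
  methods::new("ImportanceReport", edgeScores = E, topEdges = topEdges,
               nodeScores = numeric(), topFraction = topFraction)
}

#' Node-lesion importance
#'
#' Scores each ROI by the drop in cross-validated classification accuracy
#' when the node is lesioned: its screened feature row is zeroed and its
#' edges are removed from both graphs (Laplacians rebuilt with the
#' isolated-node convention), and the per-fold models are retrained under
#' the lesion with the same fold assignment as the baseline.
#'
#' @param prep a `PreparedCohort`.
#' @param M,J,folds,seed,config,nBlocks,numTrees as in [crossValidate()].
#' @param baseline optional precomputed baseline `idgcn_cv` (must use the
#'   same settings); computed here when NULL.
#' @return an [ImportanceReport-class] with `nodeScores` filled (length N:
#'   baseline accuracy minus lesioned accuracy).
#' @export
lesionImportance <- function(prep, M, J = 0L, folds = 5L, seed = 1L,
                             config = trainConfig(), nBlocks = 3L,
                             numTrees = 500L, baseline = NULL) {
  stopifnot(inherits(prep, "PreparedCohort"))
  if (prep$N <= 2) stop("lesion analysis needs more than 2 ROIs")
  if (is.null(baseline))
    baseline <- .cvEngine(prep, M, J, folds, seed, config, nBlocks, numTrees)
  base <- baseline$mean[["accuracy"]]
  scores <- vapply(seq_len(prep$N), function(r) {
    cv <- .cvEngine(prep, M, J, folds, seed, config, nBlocks, numTrees,
                    lesionNode = r, foldAssign = baseline$folds)
    base - cv$mean[["accuracy"]]
  }, numeric(1))
  names(scores) <- prep$roiIds
  methods::new("ImportanceReport", edgeScores = matrix(numeric(), 0, 0),
               topEdges = data.frame(roi_i = integer(), roi_j = integer(),
                                     score = numeric()),
               nodeScores = scores, topFraction = 0)
}

#' Write an importance report as plain-text tables
#'
#' @param report an [ImportanceReport-class].
#' @param edgePath file for the ranked top edges (tab-separated; NULL to
#'   skip).
#' @param nodePath file for the node lesion scores (NULL to skip).
#' @param roiIds optional ROI labels used instead of indices.
#' @return invisibly, NULL
#' @export
writeImportance <- function(report, edgePath = NULL, nodePath = NULL,
                            roiIds = NULL) {
  if (!is.null(edgePath) && nrow(report@topEdges)) {
    df <- report@topEdges
    if (!is.null(roiIds)) {
      df$roi_i <- roiIds[df$roi_i]
      df$roi_j <- roiIds[df$roi_j]
    }
    utils::write.table(df, edgePath, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(nodePath) && length(report@nodeScores)) {
    df <- data.frame(roi = names(report@nodeScores) %||% seq_along(report@nodeScores),
                     accuracy_drop = unname(report@nodeScores))
    utils::write.table(df, nodePath, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}
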