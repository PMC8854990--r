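#' Fit random-forest feature pre-screening
#'
#' Reduces each ROI's feature row individually: for every ROI a random
#' forest is fitted on that ROI's off-diagonal static correlation features
#' (subjects x (N-1)) against the diagnosis labels, and the M columns with
#' the largest impurity-based importance are kept (ties broken towards the
#' lower neighbour index). The same procedure on the dynamic-variability
#' rows keeps J columns. Fit this on training-fold subjects only — applying
#' it to test subjects is leakage-free, refitting on them is not.
#'
#' @param staticList list of per-subject N x N correlation matrices
#'   (training subjects only).
#' @param dynamicList list of per-subject N x N dynamic-variability
#'   matrices, or NULL when J = 0.
#' @param labels 0/1 diagnosis labels, one per training subject.
#' @param M static features kept per ROI (1..N-1).
#' @param J dynamic features kept per ROI (0..N-1).
#' @param seed integer; fixes all forest randomness.
#' @param numTrees trees per forest (default 500).
#' @return a [FeatureSelection-class].
#' @export
fitScreening <- function(staticList, dynamicList, labels, M, J = 0L,
                         seed = 1L, numTrees = 500L) {
  labels <- as.integer(labels)
  n <- length(staticList)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2)
    stop("screening needs both classes present in the training labels")
  N <- nrow(staticList[[1]])
  M <- as.integer(M); J <- as.integer(J)
  if (M < 1 || M > N - 1) stop(sprintf("M = %d out of range [1, %d]", M, N - 1))
  if (J < 0 || J > N - 1) stop(sprintf("J = %d out of range [0, %d]", J, N - 1))
  if (J > 0 && is.null(dynamicList))
    stop("J > 0 requires dynamic-variability matrices")

  rankRoi <- function(mats, r, keep, seedOff) {
    neigh <- seq_len(N)[-r]
    X <- t(vapply(mats, function(m) m[r, -r], numeric(N - 1)))
    colnames(X) <- paste0("f", neigh)
    df <- data.frame(y = factor(labels), X, check.names = FALSE)
    rf <- ranger::ranger(y ~ ., data = df, num.trees = numTrees,
                         importance = "impurity", num.threads = 1,
                         seed = .deriveSeed(seed, seedOff), verbose = FALSE)
    imp <- rf$variable.importance[paste0("f", neigh)]
    neigh[order(-imp)][seq_len(keep)]   # stable order: ties to lower index
  }

  staticIdx <- vector("list", N)
  dynamicIdx <- rep(list(integer()), N)
  for (r in seq_len(N)) {
    staticIdx[[r]] <- if (M == N - 1) seq_len(N)[-r] else
      sort(rankRoi(staticList, r, M, r))
    if (J > 0)
      dynamicIdx[[r]] <- if (J == N - 1) seq_len(N)[-r] else
        sort(rankRoi(dynamicList, r, J, N + r))
  }
  methods::new("FeatureSelection", staticIdx = staticIdx,
               dynamicIdx = dynamicIdx, M = M, J = J, nRois = as.integer(N),
               seed = as.integer(seed))
}

#' Apply a fitted feature selection to one subject
#'
#' Builds the N x (M+J) model input: row r concatenates the subject's
#' static correlation row at the selected static indices with its
#' dynamic-variability row at the selected dynamic indices.
#'
#' @param staticMat subject's N x N correlation matrix.
#' @param dynamicMat subject's N x N dynamic-variability matrix (ignored
#'   when J = 0; may be NULL then).
#' @param sel a [FeatureSelection-class].
#' @return N x (M+J) numeric feature matrix.
#' @export
applyScreening <- function(staticMat, dynamicMat, sel) {
  stopifnot(methods::is(sel, "FeatureSelection"))
  N <- sel@nRois
  if (nrow(staticMat) != N || ncol(staticMat) != N)
    stop(sprintf("subject has %d ROIs but the selection was fitted for %d (atlas mismatch)",
                 nrow(staticMat), N))
  if (sel@J > 0 && (is.null(dynamicMat) || nrow(dynamicMat) != N))
    stop("dynamic matrix missing or atlas mismatch")
  out <- matrix(0, N, sel@M + sel@J)
  for (r in seq_len(N)) {
    out[r, seq_len(sel@M)] <- staticMat[r, sel@staticIdx[[r]]]
    if (sel@J > 0)
      out[r, sel@M + seq_len(sel@J)] <- dynamicMat[r, sel@dynamicIdx[[r]]]
  }
  out
}

#' Write a feature selection as a plain-text table
#'
#' One row per selected slot: roi, slot, source (static/dynamic),
#' selected_roi. Inspectable and diffable.
#'
#' @param sel a [FeatureSelection-class]
#' @param path output file (tab-separated)
#' @return invisibly, the table written
#' @export
writeSelection <- function(sel, path) {
  rows <- list()
  for (r in seq_len(sel@nRois)) {
    rows[[length(rows) + 1]] <- data.frame(
      roi = r, slot = seq_len(sel@M), source = "static",
      selected_roi = sel@staticIdx[[r]])
    if (sel@J > 0)
      rows[[length(rows) + 1]] <- data.frame(
        roi = r, slot = seq_len(sel@J), source = "dynamic",
        selected_roi = sel@dynamicIdx[[r]])
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a feature selection written by [writeSelection()]
#'
#' @param path tab-separated selection table
#' @param seed seed recorded on the returned object (informational)
#' @return a [FeatureSelection-class]
#' @export
readSelection <- function(path, seed = 0L) {
  df <- utils::read.delim(path)
  N <- max(df$roi, df$selected_roi)
  M <- sum(df$roi == df$roi[1] & df$source == "static")
  J <- sum(df$roi == df$roi[1] & df$source == "dynamic")
  staticIdx <- lapply(seq_len(N), function(r)
    as.integer(df$selected_roi[df$roi == r & df$source == "static"]))
  dynamicIdx <- lapply(seq_len(N), function(r)
    as.integer(df$selected_roi[df$roi == r & df$source == "dynamic"]))
  methods::new("FeatureSelection", staticIdx = staticIdx,
               dynamicIdx = dynamicIdx, M = as.integer(M), J = as.integer(J),
               nRois = as.integer(N), seed = as.integer(seed))
}
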