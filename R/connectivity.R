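#' Pearson functional-connectivity matrix
#'
#' Correlates every pair of ROI time courses. Rows of the result are the
#' node feature vectors fed to the network. A zero-variance ROI cannot be
#' correlated; its row and column (including the diagonal) are set to 0 and
#' a warning names it — shapes therefore stay stable across subjects.
#'
#' @param ts T x N numeric matrix, rows = time points, columns = ROIs.
#' @return N x N symmetric correlation matrix, unit diagonal (0 for
#'   zero-variance ROIs), dimnames carried over from `ts` columns.
#' @examples
#' ts <- matrix(rnorm(40), 10, 4)
#' pearsonConnectivity(ts)
#' @export
pearsonConnectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop("need at least 2 time points")
  .checkFinite(ts, "time series")
  sds <- apply(ts, 2, stats::sd)
  zv <- sds == 0
  N <- ncol(ts)
  C <- matrix(0, N, N)
  if (any(!zv)) C[!zv, !zv] <- stats::cor(ts[, !zv, drop = FALSE])
  if (any(zv)) {
    ids <- colnames(ts)
    nm <- if (is.null(ids)) paste(which(zv), collapse = ", ") else
      paste(ids[zv], collapse = ", ")
    warning(sprintf("zero-variance ROI(s) %s: correlation row/column set to 0", nm))
  }
  C <- (C + t(C)) / 2
  diag(C)[!zv] <- 1
  dimnames(C) <- list(colnames(ts), colnames(ts))
  C
}

#' Sliding-window dynamic connectivity
#'
#' Applies a rectangular sliding window to the time series and returns one
#' Pearson correlation matrix per window. Window t (1-based) covers rows
#' `(t-1)*stride + 1` to `(t-1)*stride + windowLength`; there are
#' `floor((T - windowLength)/stride) + 1` windows.
#'
#' @param ts T x N time-series matrix.
#' @param windowLength window length in time points (2..T).
#' @param stride step between window starts (>= 1).
#' @return list of N x N correlation matrices, one per window.
#' @examples
#' ts <- matrix(rnorm(400), 100, 4)
#' length(slidingWindowConnectivity(ts, 30, 10)) # 8 windows
#' @export
slidingWindowConnectivity <- function(ts, windowLength = 30L, stride = 10L) {
  ts <- as.matrix(ts)
  T <- nrow(ts)
  if (windowLength > T)
    stop(sprintf("windowLength (%d) exceeds number of time points (%d)",
                 windowLength, T))
  if (windowLength < 2) stop("windowLength must be at least 2")
  if (stride < 1) stop("stride must be at least 1")
  nW <- floor((T - windowLength) / stride) + 1
  lapply(seq_len(nW), function(t) {
    rows <- seq.int((t - 1) * stride + 1, length.out = windowLength)
    pearsonConnectivity(ts[rows, , drop = FALSE])
  })
}

#' Temporal variability of dynamic connectivity
#'
#' Per-edge population standard deviation (divide-by-n) of the windowed
#' correlations: the auxiliary dynamic feature matrix. The diagonal is
#' forced to 0.
#'
#' @param windows list of N x N correlation matrices from
#'   [slidingWindowConnectivity()] (at least 2).
#' @return N x N symmetric non-negative matrix with zero diagonal.
#' @export
dynamicVariation <- function(windows) {
  if (length(windows) < 2)
    stop("temporal variation undefined for fewer than 2 windows")
  N <- nrow(windows[[1]])
  arr <- array(unlist(windows), dim = c(N, N, length(windows)))
  mu <- apply(arr, c(1, 2), mean)
  v <- apply(arr, c(1, 2), function(x) mean((x - mean(x))^2))
  Fm <- sqrt(v)
  Fm <- (Fm + t(Fm)) / 2
  diag(Fm) <- 0
  dimnames(Fm) <- dimnames(windows[[1]])
  Fm
}

#' Static and dynamic connectivity for every subject of a cohort
#'
#' Convenience wrapper: computes (and caches) each subject's full-series
#' correlation matrix and, when raw series are available, the
#' sliding-window variability matrix.
#'
#' @param cohort a [Cohort-class].
#' @param windowLength,stride sliding-window settings (see
#'   [slidingWindowConnectivity()]).
#' @param dynamic compute dynamic variability matrices too?
#' @return list with elements `static` (list of N x N matrices) and
#'   `dynamic` (list of N x N matrices, or NULL when `dynamic = FALSE`).
#' @export
cohortConnectivity <- function(cohort, windowLength = 30L, stride = 10L,
                               dynamic = TRUE) {
  stopifnot(methods::is(cohort, "Cohort"))
  n <- nSubjects(cohort)
  static <- vector("list", n)
  dyn <- if (dynamic) vector("list", n) else NULL
  for (s in seq_len(n)) {
    ts <- cohort@series[[s]]
    if (is.null(ts)) {
      if (dynamic)
        stop("dynamic features requested but cohort has no raw time series")
      static[[s]] <- cohort@connectivity[[s]]
      next
    }
    static[[s]] <- pearsonConnectivity(ts)
    if (dynamic)
      dyn[[s]] <- dynamicVariation(
        slidingWindowConnectivity(ts, windowLength, stride))
  }
  list(static = static, dynamic = dyn)
}
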