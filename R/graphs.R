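#' k-nearest functional graph
#'
#' For each node, keeps the k neighbours with largest absolute correlation
#' (strong anti-correlations count as strong connections; edge weights must
#' be non-negative for the normalized Laplacian). The result is symmetrised
#' by union — an edge is retained if either endpoint selected it — so every
#' node keeps at least k neighbours. Ties are broken towards the lower ROI
#' index.
#'
#' @param X N x N correlation matrix.
#' @param k neighbours per node, 1 <= k <= N-1.
#' @return a [SparseGraph-class] with weights |X_ij| on retained edges.
#' @examples
#' X <- pearsonConnectivity(matrix(rnorm(200), 20, 10))
#' knnFunctionalGraph(X, 3)
#' @export
knnFunctionalGraph <- function(X, k) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (k < 1 || k > N - 1)
    stop(sprintf("k = %d out of range [1, %d]", k, N - 1))
  S <- abs(X)
  diag(S) <- -Inf
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    sel <- order(S[i, ], decreasing = TRUE)[seq_len(k)]
    A[i, sel] <- abs(X[i, sel])
  }
  A <- pmax(A, t(A))
  diag(A) <- 0
  dimnames(A) <- dimnames(X)
  methods::new("SparseGraph", adjacency = A, kind = "functional", k = as.integer(k))
}

#' k-nearest spatial graph
#'
#' The skeleton keeps, for each node, the k spatially nearest neighbours by
#' Euclidean distance between ROI centroids (ties towards the lower index;
#' duplicated coordinates are allowed — distance 0 sorts first), symmetrised
#' by union. Retained edges are weighted by the absolute correlation
#' |X_ij|, so the spatial graph carries functional weights on an anatomical
#' skeleton.
#'
#' @param coords N x 3 matrix of ROI centroid coordinates.
#' @param X N x N correlation matrix supplying the edge weights.
#' @param k neighbours per node, 1 <= k <= N-1.
#' @return a [SparseGraph-class] of kind `"spatial"`.
#' @export
knnSpatialGraph <- function(coords, X, k) {
  coords <- as.matrix(coords)
  X <- as.matrix(X)
  N <- nrow(coords)
  if (nrow(X) != N) stop("coords and X disagree on the number of ROIs")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (k < 1 || k > N - 1)
    stop(sprintf("k = %d out of range [1, %d]", k, N - 1))
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  A <- matrix(0, N, N)
  sel <- matrix(FALSE, N, N)
  for (i in seq_len(N)) sel[i, order(D[i, ])[seq_len(k)]] <- TRUE
  sel <- sel | t(sel)
  A[sel] <- abs(X)[sel]
  diag(A) <- 0
  dimnames(A) <- dimnames(X)
  methods::new("SparseGraph", adjacency = A, kind = "spatial", k = as.integer(k))
}

#' Normalized graph Laplacian
#'
#' L = I - D^{-1/2} A D^{-1/2} with D the diagonal weighted-degree matrix.
#' Isolated nodes (degree 0) use the convention D^{-1/2} = 0, so their
#' diagonal entry is 1. The spectrum of L lies in [0, 2].
#'
#' @param g a [SparseGraph-class].
#' @return a [ScaledLaplacian-class] with the `L` slot filled (apply
#'   [scaledLaplacian()] to complete the rescaling).
#' @export
normalizedLaplacian <- function(g) {
  A <- if (methods::is(g, "SparseGraph")) g@adjacency else as.matrix(g)
  if (any(A < 0)) stop("adjacency weights must be non-negative")
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(nrow(A)) - A * outer(dinv, dinv)
  L <- (L + t(L)) / 2
  methods::new("ScaledLaplacian", L = L,
               Ltilde = matrix(numeric(), 0, 0), lambdaMax = numeric())
}

#' Rescaled Laplacian for Chebyshev filtering
#'
#' Computes lambdaMax (the exact largest eigenvalue of L) and
#' Ltilde = (2/lambdaMax) L - I, whose spectrum lies in [-1, 1] — the
#' domain on which the Chebyshev polynomial filters are defined. For a
#' degenerate edgeless graph (L = I) the fallback lambdaMax = 2 is used,
#' giving the zero operator.
#'
#' @param lap a [ScaledLaplacian-class] from [normalizedLaplacian()].
#' @return the same object with `Ltilde` and `lambdaMax` filled in.
#' @export
scaledLaplacian <- function(lap) {
  stopifnot(methods::is(lap, "ScaledLaplacian"))
  L <- lap@L
  edgeless <- max(abs(L - diag(nrow(L)))) < 1e-14
  lmax <- if (edgeless) 2 else max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (lmax <= 0) lmax <- 2
  Lt <- (2 / lmax) * L - diag(nrow(L))
  Lt <- (Lt + t(Lt)) / 2
  methods::new("ScaledLaplacian", L = L, Ltilde = Lt, lambdaMax = lmax)
}

#' Graph to rescaled Laplacian in one step
#'
#' @param g a [SparseGraph-class]
#' @return a completed [ScaledLaplacian-class]
#' @export
graphLaplacian <- function(g) scaledLaplacian(normalizedLaplacian(g))

#' Write a graph as a weighted edge list
#'
#' @param g a [SparseGraph-class]
#' @param path output file (tab-separated: i, j, weight; i < j)
#' @return invisibly, the edge-list data.frame
#' @export
writeEdgeList <- function(g, path) {
  A <- g@adjacency
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], weight = A[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
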