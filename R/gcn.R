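#' Chebyshev polynomial basis of the rescaled Laplacian
#'
#' T_0 = I, T_1 = Ltilde, T_k = 2 Ltilde T_{k-1} - T_{k-2}. These K
#' matrices define the spectral filter as a degree-(K-1) polynomial in the
#' rescaled Laplacian, avoiding any eigendecomposition at run time.
#'
#' @param Ltilde rescaled Laplacian matrix (or a [ScaledLaplacian-class]).
#' @param K number of polynomial orders (>= 1).
#' @return list of K matrices `T_0 ... T_{K-1}`.
#' @export
chebyshevBasis <- function(Ltilde, K) {
  if (methods::is(Ltilde, "ScaledLaplacian")) Ltilde <- Ltilde@Ltilde
  stopifnot(K >= 1, nrow(Ltilde) == ncol(Ltilde))
  N <- nrow(Ltilde)
  Ts <- vector("list", K)
  Ts[[1]] <- diag(N)
  if (K >= 2) Ts[[2]] <- Ltilde
  if (K >= 3) for (k in 3:K) Ts[[k]] <- 2 * Ltilde %*% Ts[[k - 1]] - Ts[[k - 2]]
  Ts
}

# forward pass with cache (for backprop): out = act(sum_k T_k X W_k)
.gcnForward <- function(X, basis, Wlist, activation = "relu") {
  K <- length(Wlist)
  S <- vector("list", K)
  A <- matrix(0, nrow(X), ncol(Wlist[[1]]))
  for (k in seq_len(K)) {
    S[[k]] <- basis[[k]] %*% X
    A <- A + S[[k]] %*% Wlist[[k]]
  }
  out <- if (activation == "relu") .relu(A) else A
  list(out = out, S = S, A = A)
}

# gradient of .gcnForward: returns dX and the list dW
.gcnBackward <- function(dOut, cache, basis, Wlist, activation = "relu") {
  dA <- if (activation == "relu") dOut * .reluGrad(cache$A) else dOut
  K <- length(Wlist)
  dW <- vector("list", K)
  dX <- matrix(0, nrow(dA), nrow(Wlist[[1]]))
  for (k in seq_len(K)) {
    dW[[k]] <- crossprod(cache$S[[k]], dA)
    dX <- dX + crossprod(basis[[k]], dA %*% t(Wlist[[k]]))
  }
  list(dX = dX, dW = dW)
}

#' Chebyshev graph-convolution layer forward pass
#'
#' Propagation rule: X_out = sigma( sum_{k=0}^{K-1} T_k(Ltilde) X W_k ),
#' with one trainable F_in x F_out weight matrix per polynomial order.
#'
#' @param X N x F_in node-feature matrix.
#' @param basis Chebyshev basis from [chebyshevBasis()] (length K).
#' @param params list with `W` (list of K weight matrices) and optionally
#'   `activation` ("relu" or "identity", default "relu").
#' @return N x F_out output feature matrix.
#' @export
gcnLayerForward <- function(X, basis, params) {
  Wlist <- params$W
  activation <- params$activation %||% "relu"
  if (length(basis) != length(Wlist))
    stop(sprintf("basis length %d != number of weight matrices %d",
                 length(basis), length(Wlist)))
  if (nrow(X) != nrow(basis[[1]]))
    stop(sprintf("feature rows (%d) != graph nodes (%d)", nrow(X), nrow(basis[[1]])))
  if (ncol(X) != nrow(Wlist[[1]]))
    stop(sprintf("feature columns (%d) != weight input dim (%d)",
                 ncol(X), nrow(Wlist[[1]])))
  .gcnForward(X, basis, Wlist, activation)$out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spectral-domain graph filter (eigendecomposition oracle)
#'
#' Applies the Chebyshev filter in the eigenbasis of the normalized
#' Laplacian: L = U Lambda U^T, Lambda_tilde = (2/lambdaMax) Lambda - I,
#' out = U (sum_k beta_k T_k(Lambda_tilde)) U^T X, with scalar coefficients
#' beta_k. Mathematically identical to the polynomial-in-Ltilde form used
#' by [gcnLayerForward()] with diagonal weights; kept as an independent
#' implementation for verification.
#'
#' @param X N x F node-feature matrix.
#' @param L normalized Laplacian (or [ScaledLaplacian-class]).
#' @param coefficients numeric vector of scalar filter coefficients, one
#'   per polynomial order.
#' @return N x F filtered feature matrix.
#' @export
spectralOracleForward <- function(X, L, coefficients) {
  if (methods::is(L, "ScaledLaplacian")) L <- L@L
  eig <- eigen(L, symmetric = TRUE)
  lmax <- max(eig$values)
  if (max(abs(L - diag(nrow(L)))) < 1e-14) lmax <- 2
  lamt <- (2 / lmax) * eig$values - 1
  K <- length(coefficients)
  # scalar Chebyshev recurrence on the eigenvalues
  Tk <- matrix(0, length(lamt), K)
  Tk[, 1] <- 1
  if (K >= 2) Tk[, 2] <- lamt
  if (K >= 3) for (k in 3:K) Tk[, k] <- 2 * lamt * Tk[, k - 1] - Tk[, k - 2]
  filt <- as.vector(Tk %*% coefficients)
  eig$vectors %*% (filt * crossprod(eig$vectors, X))
}
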