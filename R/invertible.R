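#' Additive coupling with arbitrary functions
#'
#' The invertible coupling used by every block, for any functions phi and
#' omega (they need not be invertible themselves):
#' y1 = x1 + phi(x2); y2 = x2 + omega(y1); z1 = (y1 + y2)/2;
#' z2 = (y2 - y1)/2. [coupleInverse()] undoes it exactly.
#'
#' @param x1,x2 equal-shape numeric matrices.
#' @param phi,omega functions mapping a matrix to one of the same shape.
#' @return list with elements `z1`, `z2`.
#' @export
coupleForward <- function(x1, x2, phi, omega) {
  if (!all(dim(x1) == dim(x2)))
    stop(sprintf("x1 (%dx%d) and x2 (%dx%d) must have the same shape",
                 nrow(x1), ncol(x1), nrow(x2), ncol(x2)))
  y1 <- x1 + phi(x2)
  y2 <- x2 + omega(y1)
  list(z1 = 0.5 * (y1 + y2), z2 = 0.5 * (y2 - y1))
}

#' Exact inverse of the additive coupling
#'
#' y1 = z1 - z2; y2 = z1 + z2; x2 = y2 - omega(y1); x1 = y1 - phi(x2).
#'
#' @param z1,z2 equal-shape numeric matrices.
#' @param phi,omega the same functions passed to [coupleForward()].
#' @return list with elements `x1`, `x2`.
#' @export
coupleInverse <- function(z1, z2, phi, omega) {
  if (!all(dim(z1) == dim(z2)))
    stop(sprintf("z1 (%dx%d) and z2 (%dx%d) must have the same shape",
                 nrow(z1), ncol(z1), nrow(z2), ncol(z2)))
  y1 <- z1 - z2
  y2 <- z1 + z2
  x2 <- y2 - omega(y1)
  x1 <- y1 - phi(x2)
  list(x1 = x1, x2 = x2)
}

#' Invertible block forward pass
#'
#' One additive invertible block coupling the spatial-graph GCN (phi) and
#' the functional-graph GCN (omega). Feature dimension is preserved
#' (required by the x + phi(x) addition).
#'
#' @param x1,x2 N x F feature matrices.
#' @param params block parameters: `list(phi = list(W = ...), omega =
#'   list(W = ...))`, each a Chebyshev weight stack (see
#'   [gcnLayerForward()]).
#' @param spatialBasis,functionalBasis Chebyshev bases (length K) of the
#'   spatial and functional graph Laplacians.
#' @return list with `z1`, `z2`.
#' @export
blockForward <- function(x1, x2, params, spatialBasis, functionalBasis) {
  coupleForward(x1, x2,
                phi = function(v) gcnLayerForward(v, spatialBasis, params$phi),
                omega = function(v) gcnLayerForward(v, functionalBasis, params$omega))
}

#' Invertible block inverse pass
#'
#' Exact algebraic inverse of [blockForward()] with the same parameters and
#' bases.
#'
#' @inheritParams blockForward
#' @param z1,z2 N x F block outputs.
#' @return list with `x1`, `x2`.
#' @export
blockInverse <- function(z1, z2, params, spatialBasis, functionalBasis) {
  coupleInverse(z1, z2,
                phi = function(v) gcnLayerForward(v, spatialBasis, params$phi),
                omega = function(v) gcnLayerForward(v, functionalBasis, params$omega))
}

#' Forward pass through a stack of invertible blocks
#'
#' The first block receives the input features twice, (x, x); each later
#' block consumes the (z1, z2) output of its predecessor, keeping the whole
#' pre-classifier network exactly invertible.
#'
#' @param x N x F input feature matrix.
#' @param blocks list of block parameter lists (see [blockForward()]).
#' @inheritParams blockForward
#' @return list with final `z1`, `z2`.
#' @export
stackForward <- function(x, blocks, spatialBasis, functionalBasis) {
  z1 <- x; z2 <- x
  for (b in blocks) {
    out <- blockForward(z1, z2, b, spatialBasis, functionalBasis)
    z1 <- out$z1; z2 <- out$z2
  }
  list(z1 = z1, z2 = z2)
}

#' Inverse pass through a stack of invertible blocks
#'
#' Applies [blockInverse()] in reverse block order. Composed with
#' [stackForward()] it reconstructs the input pair (x, x) to numerical
#' precision.
#'
#' @param z1,z2 N x F final outputs of [stackForward()].
#' @inheritParams stackForward
#' @return list with `x1`, `x2` (both equal to the original input when the
#'   forward pass started from (x, x)).
#' @export
stackInverse <- function(z1, z2, blocks, spatialBasis, functionalBasis) {
  for (b in rev(blocks)) {
    out <- blockInverse(z1, z2, b, spatialBasis, functionalBasis)
    z1 <- out$x1; z2 <- out$x2
  }
  list(x1 = z1, x2 = z2)
}

# --- cached forward / backward used by training ------------------------------

.blockForwardCache <- function(x1, x2, params, sb, fb) {
  phi <- .gcnForward(x2, sb, params$phi$W, params$phi$activation %||% "relu")
  y1 <- x1 + phi$out
  om <- .gcnForward(y1, fb, params$omega$W, params$omega$activation %||% "relu")
  y2 <- x2 + om$out
  list(z1 = 0.5 * (y1 + y2), z2 = 0.5 * (y2 - y1), phi = phi, omega = om)
}

.blockBackward <- function(dz1, dz2, cache, params, sb, fb) {
  dy1 <- 0.5 * (dz1 - dz2)
  dy2 <- 0.5 * (dz1 + dz2)
  gom <- .gcnBackward(dy2, cache$omega, fb, params$omega$W,
                      params$omega$activation %||% "relu")
  dy1 <- dy1 + gom$dX
  dx2 <- dy2
  gphi <- .gcnBackward(dy1, cache$phi, sb, params$phi$W,
                       params$phi$activation %||% "relu")
  dx2 <- dx2 + gphi$dX
  list(dx1 = dy1, dx2 = dx2, dPhi = gphi$dW, dOmega = gom$dW)
}

.stackForwardCache <- function(x, blocks, sb, fb) {
  z1 <- x; z2 <- x
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    c_ <- .blockForwardCache(z1, z2, blocks[[i]], sb, fb)
    caches[[i]] <- c_
    z1 <- c_$z1; z2 <- c_$z2
  }
  list(z1 = z1, z2 = z2, caches = caches)
}

# returns per-block weight gradients and the gradient wrt the stack input
.stackBackward <- function(dz1, dz2, fwd, blocks, sb, fb) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    g <- .blockBackward(dz1, dz2, fwd$caches[[i]], blocks[[i]], sb, fb)
    grads[[i]] <- list(phi = g$dPhi, omega = g$dOmega)
    dz1 <- g$dx1; dz2 <- g$dx2
  }
  list(blockGrads = grads, dx = dz1 + dz2)
}
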