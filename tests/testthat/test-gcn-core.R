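test_that("Chebyshev basis base cases and zero-operator recurrence", {
  expect_equal(chebyshevBasis(matrix(0, 4, 4), 1), list(diag(4)))
  b <- chebyshevBasis(matrix(0, 4, 4), 3)
  expect_equal(b, list(diag(4), matrix(0, 4, 4), -diag(4)))
  set.seed(1)
  gb <- randomGraphBasis(5, 4)
  expect_equal(gb$basis[[1]], diag(5))
  expect_equal(gb$basis[[2]], gb$lap@Ltilde)
})

test_that("T_3 matches cos(3 arccos(lambda)) applied eigenvalue-wise", {
  set.seed(2)
  gb <- randomGraphBasis(6, 4)
  e <- eigen(gb$lap@Ltilde, symmetric = TRUE)
  lam <- pmin(pmax(e$values, -1), 1)
  T3spec <- e$vectors %*% diag(cos(3 * acos(lam))) %*% t(e$vectors)
  expect_lt(max(abs(gb$basis[[4]] - T3spec)), 1e-8)
})

test_that("layer degenerates correctly for K=1 and zero weights", {
  set.seed(3)
  gb <- randomGraphBasis(5, 1)
  X <- matrix(rnorm(15), 5, 3)
  W0 <- matrix(rnorm(12), 3, 4)
  expect_equal(
    gcnLayerForward(X, gb$basis, list(W = list(W0), activation = "identity")),
    X %*% W0)
  gb3 <- randomGraphBasis(5, 3)
  zeroW <- lapply(1:3, function(k) matrix(0, 3, 3))
  expect_equal(gcnLayerForward(X, gb3$basis, list(W = zeroW)), matrix(0, 5, 3))
  expect_error(
    gcnLayerForward(matrix(0, 4, 3), gb3$basis, list(W = zeroW)),
    "nodes")
  expect_error(
    gcnLayerForward(X, gb3$basis, list(W = zeroW[1:2])),
    "weight matrices")
})

test_that("identity filter coefficients reproduce the input", {
  set.seed(4)
  gb <- randomGraphBasis(6, 3)
  X <- matrix(rnorm(12), 6, 2)
  expect_equal(spectralOracleForward(X, gb$lap@L, c(1, 0, 0)), X,
               tolerance = 1e-10)
})

test_that("an eigenvector signal is scaled by the filter at its eigenvalue", {
  set.seed(5)
  gb <- randomGraphBasis(7, 3)
  e <- eigen(gb$lap@L, symmetric = TRUE)
  i <- 3
  beta <- c(0.3, -0.7, 0.2)
  lamT <- (2 / gb$lap@lambdaMax) * e$values[i] - 1
  expected <- (beta[1] + beta[2] * lamT + beta[3] * (2 * lamT^2 - 1))
  out <- spectralOracleForward(matrix(e$vectors[, i]), gb$lap@L, beta)
  expect_equal(out, expected * matrix(e$vectors[, i]), tolerance = 1e-8)
})

test_that("polynomial layer equals the spectral oracle on random graphs", {
  set.seed(6)
  for (trial in 1:10) {
    N <- sample(4:10, 1); K <- sample(2:5, 1)
    gb <- randomGraphBasis(N, K)
    X <- matrix(rnorm(N * 3), N, 3)
    beta <- rnorm(K)
    W <- lapply(beta, function(b) b * diag(3))
    poly <- gcnLayerForward(X, gb$basis, list(W = W, activation = "identity"))
    spec <- spectralOracleForward(X, gb$lap@L, beta)
    expect_lt(max(abs(poly - spec)), 1e-8)
  }
})

test_that("the layer is permutation-equivariant", {
  set.seed(7)
  N <- 6; K <- 3
  gb <- randomGraphBasis(N, K)
  X <- matrix(rnorm(N * 2), N, 2)
  W <- lapply(1:K, function(k) matrix(rnorm(4), 2, 2))
  p <- sample(N)
  P <- diag(N)[p, ]
  Lp <- P %*% gb$lap@Ltilde %*% t(P)
  out <- gcnLayerForward(X, gb$basis, list(W = W))
  outP <- gcnLayerForward(P %*% X, chebyshevBasis(Lp, K), list(W = W))
  expect_equal(outP, P %*% out, tolerance = 1e-10)
})

test_that("analytic gradients agree with central differences", {
  set.seed(8)
  N <- 5; F <- 3; K <- 2; nBlocks <- 2; nSites <- 2
  sb <- randomGraphBasis(N, K)$basis
  fb <- randomGraphBasis(N, K)$basis
  feat <- matrix(rnorm(N * F), N, F)
  site <- c(1, 0)
  y <- 1L
  D <- 2 * N * F + nSites
  params <- idgcn:::.initParams(nBlocks, K, F, D, seed = 8, initSd = 0.3)
  params$fcW <- matrix(rnorm(2 * D, sd = 0.2), 2, D)
  params$fcB <- rnorm(2)
  lossAt <- function(p) {
    st <- idgcn:::.netForward(p, feat, sb, fb, site, "relu")
    crossEntropy(y, st$p[2])
  }
  st <- idgcn:::.netForward(params, feat, sb, fb, site, "relu")
  g <- idgcn:::.netBackward(params, st, y, sb, fb, nSites, "relu")
  h <- 1e-6
  checkLeaf <- function(getter, setter, gval, label) {
    for (rep in 1:3) {
      i <- sample(length(getter(params)), 1)
      pp <- params; pm <- params
      pp <- setter(pp, i, getter(pp)[i] + h)
      pm <- setter(pm, i, getter(pm)[i] - h)
      num <- (lossAt(pp) - lossAt(pm)) / (2 * h)
      ana <- getter(gval)[i]
      expect_lt(abs(num - ana) / max(1, abs(ana)), 1e-4, label = label)
    }
  }
  checkLeaf(function(p) p$fcW,
            function(p, i, v) { p$fcW[i] <- v; p }, g, "fcW")
  for (b in 1:nBlocks) for (mod in c("phi", "omega")) for (k in 1:K) {
    checkLeaf(function(p) p$blocks[[b]][[mod]][[k]],
              function(p, i, v) { p$blocks[[b]][[mod]][[k]][i] <- v; p },
              g, sprintf("block %d %s W%d", b, mod, k))
  }
})
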