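zeroF <- function(v) v * 0

test_that("zero coupling functions reduce to average and half-difference", {
  set.seed(1)
  x1 <- matrix(rnorm(12), 4, 3); x2 <- matrix(rnorm(12), 4, 3)
  out <- coupleForward(x1, x2, zeroF, zeroF)
  expect_equal(out$z1, 0.5 * (x1 + x2))
  expect_equal(out$z2, 0.5 * (x2 - x1))
  sym <- coupleForward(x1, x1, zeroF, zeroF)
  expect_equal(sym$z1, x1)
  expect_equal(sym$z2, matrix(0, 4, 3))
  inv <- coupleInverse(x1, matrix(0, 4, 3), zeroF, zeroF)
  expect_equal(inv$x1, x1)
  expect_equal(inv$x2, x1)
})

test_that("coupling inverts exactly for arbitrary nonlinear functions", {
  set.seed(2)
  for (trial in 1:100) {
    n <- sample(2:6, 1); m <- sample(1:4, 1)
    A1 <- matrix(rnorm(m * m), m, m); A2 <- matrix(rnorm(m * m), m, m)
    phi <- function(v) tanh(v %*% A1) + sin(v)
    omega <- function(v) (v %*% A2)^2 / (1 + abs(v %*% A2)) - 0.3 * v
    x1 <- matrix(rnorm(n * m), n, m); x2 <- matrix(rnorm(n * m), n, m)
    z <- coupleForward(x1, x2, phi, omega)
    back <- coupleInverse(z$z1, z$z2, phi, omega)
    expect_lt(max(abs(back$x1 - x1), abs(back$x2 - x2)), 1e-9)
    # forward-of-inverse, composed the other way
    fwd <- coupleForward(back$x1, back$x2, phi, omega)
    expect_lt(max(abs(fwd$z1 - z$z1), abs(fwd$z2 - z$z2)), 1e-9)
  }
})

test_that("GCN blocks invert with random parameters", {
  set.seed(3)
  N <- 6; F <- 4; K <- 3
  sb <- randomGraphBasis(N, K)$basis
  fb <- randomGraphBasis(N, K)$basis
  for (trial in 1:20) {
    b <- randomBlocks(1, K, F)[[1]]
    x1 <- matrix(rnorm(N * F), N, F); x2 <- matrix(rnorm(N * F), N, F)
    z <- blockForward(x1, x2, b, sb, fb)
    back <- blockInverse(z$z1, z$z2, b, sb, fb)
    expect_lt(max(abs(back$x1 - x1), abs(back$x2 - x2)), 1e-10)
  }
  expect_error(blockForward(x1, matrix(0, 2, 2), b, sb, fb), "same shape")
})

test_that("zero-parameter stacks follow the coupling algebra and invert", {
  N <- 5; F <- 3; K <- 2
  sb <- chebyshevBasis(matrix(0, N, N), K)
  fb <- sb
  zeroBlocks <- lapply(1:3, function(i) list(
    phi = list(W = lapply(1:K, function(k) matrix(0, F, F))),
    omega = list(W = lapply(1:K, function(k) matrix(0, F, F)))))
  x <- matrix(rnorm(N * F), N, F)
  # with zero functions one block maps (a, b) to ((a+b)/2, (b-a)/2):
  # (x, x) -> (x, 0) -> (x/2, -x/2) -> (0, -x/2)
  one <- stackForward(x, zeroBlocks[1], sb, fb)
  expect_equal(one$z1, x)
  expect_equal(one$z2, matrix(0, N, F))
  out <- stackForward(x, zeroBlocks, sb, fb)
  expect_equal(out$z1, matrix(0, N, F))
  expect_equal(out$z2, -x / 2)
  back <- stackInverse(out$z1, out$z2, zeroBlocks, sb, fb)
  expect_equal(back$x1, x)
  expect_equal(back$x2, x)
})

test_that("a single-block stack reduces to the block applied to (x, x)", {
  set.seed(4)
  N <- 5; F <- 3; K <- 2
  sb <- randomGraphBasis(N, K)$basis
  fb <- randomGraphBasis(N, K)$basis
  b <- randomBlocks(1, K, F)
  x <- matrix(rnorm(N * F), N, F)
  expect_equal(stackForward(x, b, sb, fb), blockForward(x, x, b[[1]], sb, fb))
})

test_that("the 3-block stack round-trips and is sensitive to perturbation", {
  set.seed(5)
  N <- 6; F <- 4; K <- 3
  sb <- randomGraphBasis(N, K)$basis
  fb <- randomGraphBasis(N, K)$basis
  blocks <- randomBlocks(3, K, F)
  x <- matrix(rnorm(N * F), N, F)
  z <- stackForward(x, blocks, sb, fb)
  back <- stackInverse(z$z1, z$z2, blocks, sb, fb)
  expect_lt(max(abs(back$x1 - x), abs(back$x2 - x)), 1e-9)
  pert <- stackInverse(z$z1 + 0.01, z$z2, blocks, sb, fb)
  expect_gt(max(abs(pert$x1 - back$x1)), 1e-4)
})
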