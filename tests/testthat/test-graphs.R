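test_that("k = N-1 keeps the complete graph with |correlation| weights", {
  set.seed(1)
  X <- randomCorrMatrix(6)
  g <- knnFunctionalGraph(X, 5)
  expected <- abs(X); diag(expected) <- 0
  expect_equal(adjacency(g), expected)
})

test_that("functional top-k selection matches a hand enumeration", {
  X <- rbind(c(1.0, 0.9, -0.2, 0.1),
             c(0.9, 1.0, 0.3, -0.8),
             c(-0.2, 0.3, 1.0, 0.5),
             c(0.1, -0.8, 0.5, 1.0))
  g <- knnFunctionalGraph(X, 1)
  # per-row strongest |r|: 1->2 (.9), 2->1 (.9), 3->4 (.5), 4->2 (.8); union
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 0.9
  A[3, 4] <- A[4, 3] <- 0.5
  A[4, 2] <- A[2, 4] <- 0.8
  expect_equal(adjacency(g), A)
  expect_error(knnFunctionalGraph(X, 4), "out of range")
})

test_that("ties go to the lower ROI index", {
  N <- 5
  X <- matrix(0.4, N, N); diag(X) <- 1
  g <- knnFunctionalGraph(X, 2)
  # every node picks the 2 lowest-index others; union of those selections
  sel <- matrix(FALSE, N, N)
  for (i in 1:N) sel[i, setdiff(1:N, i)[1:2]] <- TRUE
  sel <- sel | t(sel)
  expect_equal(adjacency(g) > 0, sel, ignore_attr = TRUE)
})

test_that("spatial skeleton of 3 collinear nodes with k=1 is the chain", {
  coords <- cbind(c(0, 10, 20), 0, 0)
  X <- matrix(0.5, 3, 3); diag(X) <- 1
  g <- knnSpatialGraph(coords, X, 1)
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.5   # 1 and 2 pick each other; 3 picks 2; union
  A[2, 3] <- A[3, 2] <- 0.5
  expect_equal(adjacency(g), A, ignore_attr = TRUE)
})

test_that("spatial graph with k = N-1 equals the complete functional weights", {
  set.seed(2)
  X <- randomCorrMatrix(5)
  coords <- matrix(runif(15, -50, 50), 5, 3)
  expect_equal(adjacency(knnSpatialGraph(coords, X, 4)),
               adjacency(knnFunctionalGraph(X, 4)))
})

test_that("graph construction is permutation-equivariant", {
  set.seed(3)
  N <- 7
  X <- randomCorrMatrix(N)
  coords <- matrix(runif(3 * N, -60, 60), N, 3)
  p <- sample(N)
  P <- diag(N)[p, ]
  for (build in list(function(X_, c_) adjacency(knnFunctionalGraph(X_, 3)),
                     function(X_, c_) adjacency(knnSpatialGraph(c_, X_, 3)))) {
    A <- build(X, coords)
    Ap <- build(X[p, p], coords[p, , drop = FALSE])
    expect_equal(Ap, (P %*% A %*% t(P)), ignore_attr = TRUE)
  }
})

test_that("normalized Laplacian matches closed forms", {
  # edgeless graph
  g0 <- methods::new("SparseGraph", adjacency = matrix(0, 3, 3),
                     kind = "functional", k = 1L)
  expect_equal(normalizedLaplacian(g0)@L, diag(3))
  # two nodes, one unit edge
  g2 <- methods::new("SparseGraph", adjacency = rbind(c(0, 1), c(1, 0)),
                     kind = "functional", k = 1L)
  lap <- normalizedLaplacian(g2)
  expect_equal(lap@L, rbind(c(1, -1), c(-1, 1)))
  expect_equal(sort(eigen(lap@L, symmetric = TRUE)$values), c(0, 2))
})

test_that("connected graphs have null eigenvector proportional to sqrt(degree)", {
  set.seed(4)
  gb <- randomGraphBasis(8, 3)
  L <- gb$lap@L
  d <- rowSums(adjacency(gb$graph))
  v <- sqrt(d)
  expect_lt(max(abs(L %*% v)), 1e-10)
  expect_gt(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
})

test_that("rescaled Laplacian has spectrum in [-1, 1] and known small cases", {
  g2 <- methods::new("SparseGraph", adjacency = rbind(c(0, 1), c(1, 0)),
                     kind = "functional", k = 1L)
  sl <- graphLaplacian(g2)
  expect_equal(sl@lambdaMax, 2)
  expect_equal(sl@Ltilde, rbind(c(0, -1), c(-1, 0)))
  # edgeless fallback lambdaMax = 2 gives the zero operator
  g0 <- methods::new("SparseGraph", adjacency = matrix(0, 4, 4),
                     kind = "functional", k = 1L)
  sl0 <- graphLaplacian(g0)
  expect_equal(sl0@lambdaMax, 2)
  expect_equal(sl0@Ltilde, matrix(0, 4, 4))
  set.seed(5)
  sl8 <- randomGraphBasis(8, 2)$lap
  ev <- eigen(sl8@Ltilde, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(ev)), 1 + 1e-9)
})

test_that("graphs from random subjects satisfy the sparse-graph invariants", {
  set.seed(6)
  co <- smallPlantedCohort(nPerClass = 10, nRois = 10, seed = 6)
  for (s in seq_len(20)) {
    X <- pearsonConnectivity(co@series[[s]])
    for (g in list(knnFunctionalGraph(X, 3),
                   knnSpatialGraph(roiCoords(co), X, 3))) {
      A <- adjacency(g)
      expect_lt(max(abs(A - t(A))), 1e-12)
      expect_true(all(A >= 0))
      expect_true(all(diag(A) == 0))
      expect_true(all(colSums(A > 0) >= 3))  # union keeps at least k
    }
  }
})

test_that("edge lists round-trip the retained edges", {
  set.seed(7)
  g <- randomGraphBasis(6, 2)$graph
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- writeEdgeList(g, f)
  back <- read.delim(f)
  expect_equal(back, df, ignore_attr = TRUE)
  expect_equal(nrow(back), sum(adjacency(g)[upper.tri(adjacency(g))] > 0))
})
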