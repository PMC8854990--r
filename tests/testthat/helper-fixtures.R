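# shared in-code fixtures; everything is generated, nothing read from disk

# random symmetric "correlation-like" matrix with unit diagonal
randomCorrMatrix <- function(N, T = 4 * N) {
  pearsonConnectivity(matrix(rnorm(T * N), T, N))
}

# random sparse graph + completed Laplacian + Chebyshev basis
randomGraphBasis <- function(N, K, k = max(1L, min(3L, N - 1L))) {
  X <- randomCorrMatrix(N)
  g <- knnFunctionalGraph(X, k)
  list(graph = g, lap = graphLaplacian(g), basis = chebyshevBasis(graphLaplacian(g), K))
}

# random invertible-block parameter stacks (phi/omega weight lists)
randomBlocks <- function(nBlocks, K, F, sd = 0.3) {
  lapply(seq_len(nBlocks), function(i) list(
    phi = list(W = lapply(seq_len(K), function(k) matrix(rnorm(F * F, sd = sd), F, F))),
    omega = list(W = lapply(seq_len(K), function(k) matrix(rnorm(F * F, sd = sd), F, F)))))
}

# small two-class cohort with planted static effect on edges (1,2),(3,4),(5,6)
smallPlantedCohort <- function(nPerClass = 20, nRois = 12, nTimepoints = 100,
                               staticEffect = 0.5, dynamicEffect = 0, seed = 42) {
  simulateCohort(cohortSpec(nPerClass, nRois = nRois, nTimepoints = nTimepoints,
    informativeEdges = rbind(c(1, 2), c(3, 4), c(5, 6)),
    staticEffect = staticEffect, dynamicEffect = dynamicEffect, seed = seed))
}
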