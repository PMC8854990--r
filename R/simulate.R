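#' Specification for a synthetic two-class cohort
#'
#' Bundles the generator settings for [simulateCohort()]. The generator
#' plants between-class differences on a chosen sparse set of ROI pairs
#' ("informative edges") through a shared latent-signal mixing model: ROIs i
#' and j of an informative edge receive a common latent component with
#' weight sqrt(rho), giving population correlation rho between them. Class 1
#' shifts rho by `staticEffect`, and (if `dynamicEffect > 0`) multiplies the
#' latent component by a slowly varying sinusoidal amplitude, normalised to
#' unit root-mean-square power so the static correlation is preserved while
#' the sliding-window correlation fluctuates more in class 1.
#'
#' @param nPerClass subjects per class.
#' @param nRois number of ROIs (graph nodes).
#' @param nTimepoints time points per subject.
#' @param informativeEdges 2-column matrix (or list of length-2 vectors) of
#'   1-based ROI index pairs carrying the planted effect.
#' @param staticEffect correlation shift on informative edges for class 1.
#' @param dynamicEffect relative amplitude (>= 0) of the sinusoidal
#'   modulation of the latent signal in class 1 subjects.
#' @param baselineCor class-0 correlation on informative edges.
#' @param nSites number of acquisition sites (assigned round-robin).
#' @param noiseSd standard deviation of additive measurement noise on the
#'   unit-variance signals; correlations are attenuated by 1/(1+noiseSd^2).
#' @param modulationPeriod period (time points) of the amplitude modulation.
#' @param seed integer seed; fully determines the cohort.
#' @return a list of class `CohortSpec`.
#' @examples
#' sp <- cohortSpec(10, informativeEdges = rbind(c(1, 2)), seed = 1)
#' @export
cohortSpec <- function(nPerClass, nRois = 20L, nTimepoints = 150L,
                       informativeEdges = matrix(integer(), 0, 2),
                       staticEffect = 0.4, dynamicEffect = 0,
                       baselineCor = 0.2, nSites = 3L, noiseSd = 0.1,
                       modulationPeriod = 100, seed = 1L) {
  if (is.list(informativeEdges))
    informativeEdges <- do.call(rbind, informativeEdges)
  informativeEdges <- matrix(as.integer(informativeEdges), ncol = 2)
  stopifnot(nPerClass >= 1, nRois >= 2, nTimepoints >= 2,
            nSites >= 1, noiseSd > 0, dynamicEffect >= 0)
  if (nrow(informativeEdges)) {
    if (min(informativeEdges) < 1 || max(informativeEdges) > nRois)
      stop("informative edge indices must lie in [1, nRois]")
    if (any(informativeEdges[, 1] == informativeEdges[, 2]))
      stop("informative edges must join distinct ROIs")
  }
  structure(list(
    nPerClass = as.integer(nPerClass), nRois = as.integer(nRois),
    nTimepoints = as.integer(nTimepoints),
    informativeEdges = informativeEdges,
    staticEffect = staticEffect, dynamicEffect = dynamicEffect,
    baselineCor = baselineCor, nSites = as.integer(nSites),
    noiseSd = noiseSd, modulationPeriod = modulationPeriod,
    seed = as.integer(seed)), class = "CohortSpec")
}

#' Generate a synthetic two-class cohort
#'
#' Draws per-subject ROI time series under the latent-signal mixing model
#' described in [cohortSpec()]: informative edges get their target
#' correlation through shared latent components; all other ROI pairs are
#' uncorrelated; class 1 optionally receives nonstationary amplitude
#' modulation (so dynamic connectivity features become informative); each
#' site adds a small constant offset (0.1 * noiseSd per site step) to all
#' series. ROI centroids are drawn once, uniformly in a 140 x 170 x 140 mm
#' box. The seed fully determines the output.
#'
#' @param spec a `CohortSpec` from [cohortSpec()].
#' @return a [Cohort-class]; class-0 subjects first, then class-1.
#' @examples
#' co <- simulateCohort(cohortSpec(5, nRois = 8, nTimepoints = 60,
#'   informativeEdges = rbind(c(1, 2)), staticEffect = 0.4, seed = 7))
#' co
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  N <- spec$nRois; T <- spec$nTimepoints
  edges <- spec$informativeEdges
  nE <- nrow(edges)
  rho0 <- rep(spec$baselineCor, nE)
  rho1 <- rho0 + spec$staticEffect
  for (e in seq_len(nE)) {
    for (rho in c(rho0[e], rho1[e])) if (abs(rho) >= 1)
      stop(sprintf("infeasible correlation target %.3f on edge (%d, %d)",
                   rho, edges[e, 1], edges[e, 2]))
  }
  # each ROI's total latent weight must leave positive residual variance
  for (cls in 0:1) {
    rho <- if (cls == 0) rho0 else rho1
    wsum <- numeric(N)
    for (e in seq_len(nE)) {
      wsum[edges[e, 1]] <- wsum[edges[e, 1]] + abs(rho[e])
      wsum[edges[e, 2]] <- wsum[edges[e, 2]] + abs(rho[e])
    }
    bad <- which(wsum >= 1)
    if (length(bad))
      stop(sprintf("infeasible correlation targets: ROI %d accumulates latent variance %.3f >= 1",
                   bad[1], wsum[bad[1]]))
  }

  nSub <- 2L * spec$nPerClass
  labels <- rep(0:1, each = spec$nPerClass)
  sites <- paste0("site", ((seq_len(nSub) - 1L) %% spec$nSites) + 1L)
  siteOffset <- 0.1 * spec$noiseSd * (match(sites, paste0("site", seq_len(spec$nSites))) - 1L)

  withr::with_seed(spec$seed, {
    coords <- cbind(stats::runif(N, -70, 70), stats::runif(N, -85, 85),
                    stats::runif(N, -70, 70))
    series <- vector("list", nSub)
    tgrid <- seq_len(T)
    for (s in seq_len(nSub)) {
      cls <- labels[s]
      rho <- if (cls == 0) rho0 else rho1
      X <- matrix(0, T, N)
      resVar <- rep(1, N)
      for (e in seq_len(nE)) {
        i <- edges[e, 1]; j <- edges[e, 2]
        l <- stats::rnorm(T)
        a <- rep(1, T)
        if (cls == 1 && spec$dynamicEffect > 0) {
          phase <- stats::runif(1, 0, 2 * pi)
          de <- spec$dynamicEffect
          a <- (1 + de * sin(2 * pi * tgrid / spec$modulationPeriod + phase)) /
            sqrt(1 + de^2 / 2)
        }
        wi <- sqrt(abs(rho[e]))
        wj <- sign(rho[e]) * sqrt(abs(rho[e]))
        X[, i] <- X[, i] + wi * a * l
        X[, j] <- X[, j] + wj * a * l
        resVar[i] <- resVar[i] - abs(rho[e])
        resVar[j] <- resVar[j] - abs(rho[e])
      }
      X <- X + matrix(stats::rnorm(T * N), T, N) %*% diag(sqrt(resVar), N)
      X <- X + spec$noiseSd * matrix(stats::rnorm(T * N), T, N)
      X <- X + siteOffset[s]
      colnames(X) <- paste0("roi", seq_len(N))
      series[[s]] <- X
    }
  })
  rownames(coords) <- paste0("roi", seq_len(N))
  colnames(coords) <- c("x", "y", "z")
  methods::new("Cohort",
    series = series, connectivity = list(), labels = as.integer(labels),
    sites = sites, coords = coords, roiIds = paste0("roi", seq_len(N)),
    truthEdges = matrix(as.integer(edges), ncol = 2,
                        dimnames = list(NULL, c("i", "j"))),
    spec = unclass(spec))
}

#' Ground-truth feature-table entries for planted edges
#'
#' Maps each planted informative edge (i, j) of a synthetic cohort to the
#' two entries of the per-ROI feature table that screening should recover:
#' (node i, neighbour j) and (node j, neighbour i) — correlation features
#' are symmetric, so both rows of the feature table carry the signal.
#'
#' @param cohort a [Cohort-class] produced by [simulateCohort()].
#' @return integer matrix with columns `node`, `neighbour` (0 rows when the
#'   cohort has no planted edges).
#' @export
groundTruthFeatureIndices <- function(cohort) {
  stopifnot(methods::is(cohort, "Cohort"))
  e <- cohort@truthEdges
  out <- rbind(e, e[, 2:1, drop = FALSE])
  out <- matrix(as.integer(out), ncol = 2, dimnames = list(NULL, c("node", "neighbour")))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}
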