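# --- parameter-structure helpers --------------------------------------------

# apply f leaf-wise over parallel nested lists of numerics/matrices
.mapStruct <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1]])) {
    out <- vector("list", length(xs[[1]]))
    names(out) <- names(xs[[1]])
    for (i in seq_along(xs[[1]]))
      out[[i]] <- do.call(.mapStruct, c(list(f), lapply(xs, `[[`, i)))
    out
  } else do.call(f, xs)
}

.sumAbsStruct <- function(p) {
  tot <- 0
  rapply(p, function(x) tot <<- tot + sum(abs(x)), how = "unlist")
  tot
}

# initial parameters: small random GCN weights (relu needs non-zero
# pre-activations for gradient flow), zero classifier
.initParams <- function(nBlocks, K, F, D, seed, initSd) {
  withr::with_seed(seed, {
    blocks <- lapply(seq_len(nBlocks), function(i) {
      mk <- function() lapply(seq_len(K), function(k)
        matrix(stats::rnorm(F * F, sd = initSd), F, F))
      list(phi = mk(), omega = mk())
    })
  })
  list(blocks = blocks, fcW = matrix(0, 2, D), fcB = c(0, 0))
}

# wrap raw weight stacks into the form the layer code expects
.blockParams <- function(blocks, activation) {
  lapply(blocks, function(b) list(
    phi = list(W = b$phi, activation = activation),
    omega = list(W = b$omega, activation = activation)))
}

#' Training configuration
#'
#' Settings for the first-order optimisation of the network. Defaults:
#' Adam, learning rate 1e-3, 100 epochs, full batch, no weight decay.
#'
#' @param epochs number of passes over the training set.
#' @param learningRate Adam step size.
#' @param batchSize subjects per gradient step (NULL = full batch).
#' @param weightDecay L2 penalty on the invertible-block weights only
#'   (default 0.05). Decaying the blocks towards zero anchors the additive
#'   coupling near the identity map, which keeps the pre-classifier
#'   representation feature-aligned — the regime in which
#'   reconstruction-based attribution is faithful. The classifier layer is
#'   never penalised.
#' @param seed integer; fixes initialisation and batch shuffling.
#' @param initSd standard deviation of the initial GCN weights.
#' @param activation activation inside phi/omega ("relu" or "identity").
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 100L, learningRate = 1e-3, batchSize = NULL,
                        weightDecay = 0.05, seed = 1L, initSd = 0.05,
                        activation = "relu") {
  stopifnot(epochs >= 1, learningRate > 0, weightDecay >= 0, initSd >= 0,
            activation %in% c("relu", "identity"))
  structure(list(epochs = as.integer(epochs), learningRate = learningRate,
                 batchSize = batchSize, weightDecay = weightDecay,
                 seed = as.integer(seed), initSd = initSd,
                 activation = activation), class = "TrainConfig")
}

# --- forward / loss -----------------------------------------------------------

# per-subject forward with caches; features N x F, site one-hot length nSites
.netForward <- function(params, feat, sb, fb, siteVec, activation) {
  bp <- .blockParams(params$blocks, activation)
  fwd <- .stackForwardCache(feat, bp, sb, fb)
  v <- c(as.vector(fwd$z1), as.vector(fwd$z2), siteVec)
  logits <- as.vector(params$fcW %*% v) + params$fcB
  p <- .softmax(logits)
  list(fwd = fwd, v = v, p = p)
}

.netBackward <- function(params, state, y, sb, fb, nSites, activation) {
  dlogits <- state$p - c(1 - y, y)
  dfcW <- outer(dlogits, state$v)
  dfcB <- dlogits
  dv <- as.vector(crossprod(params$fcW, dlogits))
  N <- nrow(state$fwd$z1); F <- ncol(state$fwd$z1)
  dz1 <- matrix(dv[seq_len(N * F)], N, F)
  dz2 <- matrix(dv[N * F + seq_len(N * F)], N, F)
  bp <- .blockParams(params$blocks, activation)
  sg <- .stackBackward(dz1, dz2, state$fwd, bp, sb, fb)
  list(blocks = sg$blockGrads, fcW = dfcW, fcB = dfcB)
}

#' Cross-entropy loss
#'
#' -y log(yhat) - (1-y) log(1-yhat), with yhat clipped to
#' [1e-12, 1 - 1e-12]. For a batch, the model loss is the mean over
#' subjects.
#'
#' @param y binary label (0/1), vectorised.
#' @param yhat predicted probability of class 1, vectorised.
#' @return non-negative loss value(s).
#' @examples
#' crossEntropy(1, 0.5)  # log(2)
#' @export
crossEntropy <- function(y, yhat) {
  yhat <- .clip(yhat)
  -y * log(yhat) - (1 - y) * log(1 - yhat)
}

# --- training -----------------------------------------------------------------

# workhorse: features/bases/onehots are aligned lists over the training set
.fitNetwork <- function(featList, sbList, fbList, onehotList, labels,
                        config, nBlocks, K) {
  n <- length(featList)
  N <- nrow(featList[[1]]); F <- ncol(featList[[1]])
  nSites <- length(onehotList[[1]])
  D <- 2L * N * F + nSites
  act <- config$activation
  params <- .initParams(nBlocks, K, F, D, config$seed, config$initSd)
  mAd <- .mapStruct(function(x) x * 0, params)
  vAd <- .mapStruct(function(x) x * 0, params)
  b1 <- 0.9; b2 <- 0.999; epsAd <- 1e-8
  lr <- config$learningRate
  batch <- if (is.null(config$batchSize)) n else min(config$batchSize, n)
  lossHistory <- numeric(config$epochs)
  step <- 0

  withr::with_seed(.deriveSeed(config$seed, 3), {
    for (ep in seq_len(config$epochs)) {
      ord <- if (batch < n) sample.int(n) else seq_len(n)
      epochLoss <- 0
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1, n)]
        grads <- .mapStruct(function(x) x * 0, params)
        for (s in idx) {
          st <- .netForward(params, featList[[s]], sbList[[s]], fbList[[s]],
                            onehotList[[s]], act)
          loss <- crossEntropy(labels[s], st$p[2])
          if (!is.finite(loss))
            stop(sprintf("training diverged: non-finite loss at epoch %d", ep))
          epochLoss <- epochLoss + loss
          g <- .netBackward(params, st, labels[s], sbList[[s]], fbList[[s]],
                            nSites, act)
          grads <- .mapStruct(`+`, grads, g)
        }
        grads <- .mapStruct(function(g) g / length(idx), grads)
        if (config$weightDecay > 0)
          grads$blocks <- .mapStruct(function(g, p) g + config$weightDecay * p,
                                     grads$blocks, params$blocks)
        step <- step + 1
        mAd <- .mapStruct(function(m, g) b1 * m + (1 - b1) * g, mAd, grads)
        vAd <- .mapStruct(function(v, g) b2 * v + (1 - b2) * g^2, vAd, grads)
        corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
        params <- .mapStruct(function(p, m, v)
          p - lr * (m / corr1) / (sqrt(v / corr2) + epsAd),
          params, mAd, vAd)
      }
      lossHistory[ep] <- epochLoss / n
    }
  })
  list(params = params, lossHistory = lossHistory)
}

#' Prepare a cohort for modelling
#'
#' Computes everything that does not depend on the train/test split:
#' per-subject static and dynamic connectivity, per-subject k-nearest
#' functional and spatial graphs with their Chebyshev bases, and the site
#' one-hot encoding.
#'
#' @param cohort a [Cohort-class].
#' @param windowLength,stride sliding-window settings.
#' @param k neighbours per node in both graphs.
#' @param K Chebyshev polynomial order.
#' @param useDynamic compute dynamic features (needed when J > 0)?
#' @param useSpatial build the spatial graph? When FALSE, phi falls back to
#'   the functional graph (spatial-information ablation).
#' @return list of class `PreparedCohort`.
#' @export
prepareCohort <- function(cohort, windowLength = 30L, stride = 10L, k = 3L,
                          K = 3L, useDynamic = TRUE, useSpatial = TRUE) {
  stopifnot(methods::is(cohort, "Cohort"))
  conn <- cohortConnectivity(cohort, windowLength, stride, dynamic = useDynamic)
  n <- nSubjects(cohort)
  N <- nRois(cohort)
  funcAdj <- vector("list", n); spatAdj <- vector("list", n)
  fb <- vector("list", n); sb <- vector("list", n)
  for (s in seq_len(n)) {
    fg <- knnFunctionalGraph(conn$static[[s]], k)
    funcAdj[[s]] <- fg@adjacency
    fb[[s]] <- chebyshevBasis(graphLaplacian(fg), K)
    if (useSpatial) {
      sg <- knnSpatialGraph(roiCoords(cohort), conn$static[[s]], k)
      spatAdj[[s]] <- sg@adjacency
      sb[[s]] <- chebyshevBasis(graphLaplacian(sg), K)
    } else {
      spatAdj[[s]] <- fg@adjacency
      sb[[s]] <- fb[[s]]
    }
  }
  siteLevels <- sort(unique(siteLabels(cohort)))
  onehots <- lapply(siteLabels(cohort), .siteOnehot, levels = siteLevels)
  structure(list(
    static = conn$static, dynamic = conn$dynamic,
    functionalAdj = funcAdj, spatialAdj = spatAdj,
    functionalBases = fb, spatialBases = sb,
    labels = subjectLabels(cohort), sites = siteLabels(cohort),
    siteLevels = siteLevels, siteOnehots = onehots,
    coords = roiCoords(cohort), roiIds = cohort@roiIds,
    truthEdges = truthEdges(cohort), n = n, N = N,
    k = as.integer(k), K = as.integer(K),
    windowLength = as.integer(windowLength), stride = as.integer(stride),
    useDynamic = useDynamic, useSpatial = useSpatial
  ), class = "PreparedCohort")
}

# screened features for a subject set; a lesioned node contributes nothing:
# its own feature row is zeroed and so is every slot of another ROI whose
# source column is the lesioned node
.screenedFeatures <- function(prep, sel, idx, lesionNode = NULL) {
  lapply(idx, function(s) {
    f <- applyScreening(prep$static[[s]],
                        if (sel@J > 0) prep$dynamic[[s]] else NULL, sel)
    if (!is.null(lesionNode)) {
      f[lesionNode, ] <- 0
      for (r in seq_len(sel@nRois)) {
        f[r, which(sel@staticIdx[[r]] == lesionNode)] <- 0
        if (sel@J > 0)
          f[r, sel@M + which(sel@dynamicIdx[[r]] == lesionNode)] <- 0
      }
    }
    f
  })
}

# Chebyshev bases for a subject set, with an optional node lesioned out of
# both graphs (its edges removed; isolated-node Laplacian convention)
.basesFor <- function(prep, idx, lesionNode = NULL) {
  if (is.null(lesionNode))
    return(list(sb = prep$spatialBases[idx], fb = prep$functionalBases[idx]))
  rebuild <- function(A) {
    A[lesionNode, ] <- 0; A[, lesionNode] <- 0
    chebyshevBasis(scaledLaplacian(normalizedLaplacian(A)), prep$K)
  }
  list(sb = lapply(prep$spatialAdj[idx], rebuild),
       fb = lapply(prep$functionalAdj[idx], rebuild))
}

#' Train an invertible dynamic GCN
#'
#' Fits the 3-block (by default) invertible network plus fully connected
#' softmax classifier by Adam on the mean cross-entropy, using analytic
#' gradients. Deterministic for a fixed `config$seed`.
#'
#' @param prep a `PreparedCohort` from [prepareCohort()].
#' @param selection a [FeatureSelection-class] (fit it on training subjects
#'   only).
#' @param trainIdx integer indices of training subjects (default: all).
#' @param config a [trainConfig()].
#' @param nBlocks number of invertible blocks.
#' @return a trained [IDGCNModel-class]; the per-epoch training loss is in
#'   `model@config$lossHistory`.
#' @export
trainIDGCN <- function(prep, selection, trainIdx = NULL,
                       config = trainConfig(), nBlocks = 3L) {
  stopifnot(inherits(prep, "PreparedCohort"),
            methods::is(selection, "FeatureSelection"))
  if (is.null(trainIdx)) trainIdx <- seq_len(prep$n)
  y <- prep$labels[trainIdx]
  if (min(table(factor(y, levels = 0:1))) < 2)
    stop("need at least 2 training subjects per class")
  feats <- .screenedFeatures(prep, selection, trainIdx)
  bases <- .basesFor(prep, trainIdx)
  fit <- .fitNetwork(feats, bases$sb, bases$fb, prep$siteOnehots[trainIdx],
                     y, config, nBlocks, prep$K)
  F <- selection@M + selection@J
  blocks <- lapply(fit$params$blocks, function(b)
    list(phi = list(W = b$phi, activation = config$activation),
         omega = list(W = b$omega, activation = config$activation)))
  methods::new("IDGCNModel",
    blocks = blocks, fcW = fit$params$fcW, fcB = fit$params$fcB,
    K = prep$K, nRois = as.integer(prep$N), featureDim = as.integer(F),
    nSites = length(prep$siteLevels), siteLevels = prep$siteLevels,
    selection = selection,
    config = c(unclass(config), list(nBlocks = as.integer(nBlocks),
                                     lossHistory = fit$lossHistory)),
    trained = TRUE)
}

#' Model forward pass for one subject
#'
#' Runs the invertible stack on the screened features and applies the
#' fully connected softmax layer to the flattened outputs plus the site
#' one-hot covariate.
#'
#' @param model an [IDGCNModel-class].
#' @param features N x F screened feature matrix (see [applyScreening()]).
#' @param spatialBasis,functionalBasis the subject's Chebyshev bases.
#' @param site site label (matched against the model's site levels) or a
#'   numeric one-hot vector.
#' @return length-2 probability vector (class 0, class 1); sums to 1.
#' @export
modelForward <- function(model, features, spatialBasis, functionalBasis, site) {
  stopifnot(methods::is(model, "IDGCNModel"))
  siteVec <- if (is.numeric(site)) {
    if (length(site) != model@nSites)
      stop(sprintf("site one-hot has length %d, model expects %d",
                   length(site), model@nSites))
    site
  } else .siteOnehot(site, model@siteLevels)
  if (nrow(features) != model@nRois || ncol(features) != model@featureDim)
    stop(sprintf("features are %dx%d, model expects %dx%d",
                 nrow(features), ncol(features), model@nRois, model@featureDim))
  out <- stackForward(features, model@blocks, spatialBasis, functionalBasis)
  v <- c(as.vector(out$z1), as.vector(out$z2), siteVec)
  p <- .softmax(as.vector(model@fcW %*% v) + model@fcB)
  names(p) <- c("class0", "class1")
  p
}

#' Predict class-1 probabilities for cohort subjects
#'
#' @param model a trained [IDGCNModel-class].
#' @param prep the `PreparedCohort` the subjects live in.
#' @param idx subject indices (default: all).
#' @return numeric vector of class-1 probabilities.
#' @export
predictIDGCN <- function(model, prep, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(prep$n)
  feats <- .screenedFeatures(prep, model@selection, idx)
  vapply(seq_along(idx), function(i) {
    s <- idx[i]
    modelForward(model, feats[[i]], prep$spatialBases[[s]],
                 prep$functionalBases[[s]], prep$siteOnehots[[s]])[2]
  }, numeric(1))
}

# --- evaluation ---------------------------------------------------------------

#' Classification metrics from probabilities and labels
#'
#' Thresholds class-1 probabilities at 0.5 to form the confusion counts and
#' computes accuracy = (TP+TN)/n, precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2 P R/(P+R), and rank-based AUC (the normalised
#' Mann-Whitney statistic of the class-1 probabilities).
#'
#' @param prob1 class-1 probabilities.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return list of class `Metrics`: n, TP, TN, FP, FN, accuracy, auc,
#'   precision, recall, f1.
#' @export
evaluateMetrics <- function(prob1, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(prob1) == length(labels))
  pred <- as.integer(prob1 >= threshold)
  TP <- sum(pred == 1 & labels == 1); TN <- sum(pred == 0 & labels == 0)
  FP <- sum(pred == 1 & labels == 0); FN <- sum(pred == 0 & labels == 1)
  n <- length(labels)
  n1 <- sum(labels == 1); n0 <- n - n1
  auc <- if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    NA_real_
  } else {
    r <- rank(prob1)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(n = n, TP = TP, TN = TN, FP = FP, FN = FN,
                 accuracy = (TP + TN) / n, auc = auc,
                 precision = precision, recall = recall, f1 = f1),
            class = "Metrics")
}

#' @export
print.Metrics <- function(x, ...) {
  cat(sprintf(
    "Metrics (n = %d): accuracy %.3f, AUC %s, precision %s, recall %s, F1 %s\n",
    x$n, x$accuracy, format(round(x$auc, 3)), format(round(x$precision, 3)),
    format(round(x$recall, 3)), format(round(x$f1, 3))))
  invisible(x)
}

# stratified fold assignment; overall fold sizes differ by at most 1
.stratifiedFolds <- function(labels, folds, seed) {
  n <- length(labels)
  if (n < folds) stop(sprintf("%d subjects is fewer than %d folds", n, folds))
  assign <- integer(n)
  withr::with_seed(.deriveSeed(seed, 17), {
    offset <- 0
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      assign[idx] <- ((offset + seq_along(idx) - 1L) %% folds) + 1L
      offset <- offset + length(idx)
    }
  })
  assign
}

# cross-validation engine shared by crossValidate() and lesionImportance()
.cvEngine <- function(prep, M, J, folds, seed, config, nBlocks,
                      numTrees = 500L, lesionNode = NULL,
                      foldAssign = NULL, keepModels = FALSE) {
  labels <- prep$labels
  if (is.null(foldAssign)) foldAssign <- .stratifiedFolds(labels, folds, seed)
  allIdx <- seq_len(prep$n)
  lesBases <- if (!is.null(lesionNode)) .basesFor(prep, allIdx, lesionNode)
  perFold <- vector("list", folds)
  models <- vector("list", folds)
  selections <- vector("list", folds)
  probs <- rep(NA_real_, prep$n)
  for (f in seq_len(folds)) {
    trainIdx <- which(foldAssign != f)
    testIdx <- which(foldAssign == f)
    sel <- fitScreening(prep$static[trainIdx],
                        if (J > 0) prep$dynamic[trainIdx] else NULL,
                        labels[trainIdx], M, J,
                        seed = .deriveSeed(seed, 100 + f), numTrees = numTrees)
    feats <- .screenedFeatures(prep, sel, allIdx, lesionNode)
    bases <- if (is.null(lesionNode))
      list(sb = prep$spatialBases, fb = prep$functionalBases) else lesBases
    cfgF <- config
    cfgF$seed <- .deriveSeed(config$seed, 500 + f)
    fit <- .fitNetwork(feats[trainIdx], bases$sb[trainIdx], bases$fb[trainIdx],
                       prep$siteOnehots[trainIdx], labels[trainIdx],
                       cfgF, nBlocks, prep$K)
    act <- config$activation
    bp <- .blockParams(fit$params$blocks, act)
    pTest <- vapply(testIdx, function(s) {
      st <- .netForward(fit$params, feats[[s]], bases$sb[[s]], bases$fb[[s]],
                        prep$siteOnehots[[s]], act)
      st$p[2]
    }, numeric(1))
    probs[testIdx] <- pTest
    perFold[[f]] <- suppressWarnings(evaluateMetrics(pTest, labels[testIdx]))
    selections[[f]] <- sel
    if (keepModels) models[[f]] <- fit$params
  }
  metricNames <- c("accuracy", "auc", "precision", "recall", "f1")
  tab <- do.call(rbind, lapply(seq_len(folds), function(f) {
    m <- perFold[[f]]
    data.frame(fold = f, n = m$n, TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
               accuracy = m$accuracy, auc = m$auc, precision = m$precision,
               recall = m$recall, f1 = m$f1)
  }))
  structure(list(
    perFold = tab,
    mean = vapply(metricNames, function(nm) mean(tab[[nm]], na.rm = TRUE), numeric(1)),
    sd = vapply(metricNames, function(nm) stats::sd(tab[[nm]]), numeric(1)),
    folds = foldAssign, probs = probs, selections = selections,
    models = if (keepModels) models, M = M, J = J, seed = seed
  ), class = "idgcn_cv")
}

#' Stratified k-fold cross-validated evaluation
#'
#' The full pipeline under cross-validation: fold assignment is stratified
#' by class; inside every fold the random-forest screening is refitted on
#' that fold's training subjects only (no leakage), the network is trained
#' on them, and the held-out subjects are scored. Reported metrics are
#' per-fold plus mean and SD.
#'
#' @param cohort a [Cohort-class] (or pass a ready `prep`).
#' @param M,J static/dynamic features kept per ROI.
#' @param k graph neighbours; K Chebyshev order.
#' @param folds number of CV folds.
#' @param seed seed for fold assignment and screening.
#' @param config a [trainConfig()].
#' @param windowLength,stride,useDynamic,useSpatial see [prepareCohort()].
#' @param nBlocks invertible blocks in the network.
#' @param numTrees trees per screening forest.
#' @param prep optional precomputed `PreparedCohort` (overrides `cohort`).
#' @return list of class `idgcn_cv`: `perFold` (data.frame), `mean`, `sd`,
#'   `folds`, held-out `probs`, and the per-fold `selections`.
#' @export
crossValidate <- function(cohort = NULL, M = 48L, J = 10L, k = 3L, K = 3L,
                          folds = 5L, seed = 1L, config = trainConfig(),
                          windowLength = 30L, stride = 10L,
                          useDynamic = TRUE, useSpatial = TRUE,
                          nBlocks = 3L, numTrees = 500L, prep = NULL) {
  if (is.null(prep))
    prep <- prepareCohort(cohort, windowLength, stride, k, K,
                          useDynamic = useDynamic && J > 0,
                          useSpatial = useSpatial)
  .cvEngine(prep, M, J, folds, seed, config, nBlocks, numTrees)
}

#' @export
print.idgcn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (M = %d, J = %d)\n",
              nrow(x$perFold), x$M, x$J))
  for (nm in names(x$mean))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", nm, x$mean[[nm]], x$sd[[nm]]))
  invisible(x)
}
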