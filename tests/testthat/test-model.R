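test_that("metrics reproduce their formulas from hand-built counts", {
  # TP=3, TN=2, FP=1, FN=2 -> acc .625, prec .75, rec .6, F1 = 2*.75*.6/1.35
  prob <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.1, 0.3, 0.4)
  y    <- c(1,   1,   1,   0,   1,   1,   0,   0)
  m <- evaluateMetrics(prob, y)
  expect_equal(c(m$TP, m$TN, m$FP, m$FN), c(3, 2, 1, 2))
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$TP + m$TN + m$FP + m$FN, m$n)
})

test_that("perfect predictions give all-1 metrics; single class warns NA AUC", {
  m <- evaluateMetrics(c(0.9, 0.95, 0.1, 0.05), c(1, 1, 0, 0))
  expect_equal(unlist(m[c("accuracy", "auc", "precision", "recall", "f1")]),
               rep(1, 5), ignore_attr = TRUE)
  expect_warning(m1 <- evaluateMetrics(c(0.4, 0.6), c(1, 1)), "one class")
  expect_true(is.na(m1$auc))
})

test_that("rank AUC matches pROC and is ~0.5 on random scores", {
  set.seed(1)
  aucs <- replicate(50, {
    y <- rep(0:1, each = 20)
    p <- runif(40)
    m <- evaluateMetrics(p, y)
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(m$auc, ref, tolerance = 1e-12)
    m$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("cross-entropy closed forms and symmetry hold", {
  expect_equal(crossEntropy(1, 1), 0, tolerance = 1e-12)
  expect_equal(crossEntropy(1, 0.5), log(2), tolerance = 1e-12)
  for (p in c(0.1, 0.37, 0.9))
    expect_equal(crossEntropy(1, p), crossEntropy(0, 1 - p), tolerance = 1e-12)
  expect_true(is.finite(crossEntropy(1, 0)))
})

test_that("softmax classifier head behaves algebraically", {
  set.seed(2)
  N <- 5; F <- 3; K <- 2; nSites <- 2
  sel <- methods::new("FeatureSelection",
    staticIdx = lapply(1:N, function(r) setdiff(1:N, r)[1:2]),
    dynamicIdx = lapply(1:N, function(r) setdiff(1:N, r)[3]),
    M = 2L, J = 1L, nRois = 5L, seed = 0L)
  D <- 2 * N * F + nSites
  mkModel <- function(fcW) methods::new("IDGCNModel",
    blocks = lapply(randomBlocks(2, K, F, sd = 0.1), function(b)
      list(phi = list(W = b$phi$W, activation = "relu"),
           omega = list(W = b$omega$W, activation = "relu"))),
    fcW = fcW, fcB = c(0, 0), K = 2L, nRois = 5L, featureDim = 3L,
    nSites = 2L, siteLevels = c("site1", "site2"), selection = sel,
    config = list(), trained = TRUE)
  sb <- randomGraphBasis(N, K)$basis
  fb <- randomGraphBasis(N, K)$basis
  x <- matrix(rnorm(N * F), N, F)
  # zero weights -> (0.5, 0.5)
  p0 <- modelForward(mkModel(matrix(0, 2, D)), x, sb, fb, "site1")
  expect_equal(unname(p0), c(0.5, 0.5))
  # probabilities normalise, and the logit difference is linear in features
  W <- matrix(rnorm(2 * D, sd = 0.3), 2, D)
  mod <- mkModel(W)
  p <- modelForward(mod, x, sb, fb, "site2")
  expect_equal(sum(p), 1, tolerance = 1e-12)
  z <- stackForward(x, mod@blocks, sb, fb)
  v <- c(as.vector(z$z1), as.vector(z$z2), c(0, 1))
  expect_equal(log(p[2] / p[1]), sum((W[2, ] - W[1, ]) * v),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(modelForward(mod, x, sb, fb, "siteX"), "unknown site")
})

test_that("training reduces the loss and is reproducible", {
  co <- smallPlantedCohort(nPerClass = 8, nRois = 8, nTimepoints = 80,
                           staticEffect = 0.6, seed = 9)
  prep <- prepareCohort(co, k = 2, K = 2, useDynamic = FALSE)
  sel <- fitScreening(prep$static, NULL, prep$labels, M = 3, J = 0,
                      seed = 9, numTrees = 50)
  cfg <- trainConfig(epochs = 30, seed = 9)
  m1 <- trainIDGCN(prep, sel, config = cfg, nBlocks = 2)
  m2 <- trainIDGCN(prep, sel, config = cfg, nBlocks = 2)
  h <- m1@config$lossHistory
  expect_lt(h[length(h)], h[1])
  expect_identical(m1@fcW, m2@fcW)
  expect_identical(m1@blocks, m2@blocks)
  p1 <- predictIDGCN(m1, prep)
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("stratified folds balance classes and sizes", {
  y <- c(rep(0L, 23), rep(1L, 17))
  f <- idgcn:::.stratifiedFolds(y, 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  sizes <- table(f)
  expect_lte(max(sizes) - min(sizes), 1)
  perClass <- table(f, y)
  expect_lte(max(perClass[, 1]) - min(perClass[, 1]), 1)
  expect_lte(max(perClass[, 2]) - min(perClass[, 2]), 1)
  expect_error(idgcn:::.stratifiedFolds(rep(0:1, 2), 5, 1), "fewer than")
})

test_that("aggregate CV metrics are the mean and SD of the fold metrics", {
  co <- smallPlantedCohort(nPerClass = 8, nRois = 8, nTimepoints = 80,
                           staticEffect = 0.6, seed = 10)
  cv <- crossValidate(co, M = 3, J = 0, k = 2, K = 2, folds = 4, seed = 10,
                      config = trainConfig(epochs = 10, seed = 10),
                      useDynamic = FALSE, numTrees = 50)
  expect_equal(cv$mean[["accuracy"]], mean(cv$perFold$accuracy))
  expect_equal(cv$sd[["f1"]], sd(cv$perFold$f1))
  expect_equal(sum(cv$perFold$n), nSubjects(co))
})
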