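test_that("M = N-1 selects every off-diagonal column regardless of labels", {
  set.seed(1)
  mats <- replicate(8, randomCorrMatrix(5), simplify = FALSE)
  sel <- fitScreening(mats, NULL, rep(0:1, 4), M = 4, J = 0, seed = 1,
                      numTrees = 10)
  for (r in 1:5) expect_equal(sel@staticIdx[[r]], setdiff(1:5, r))
})

test_that("screening is deterministic for a fixed seed", {
  set.seed(2)
  mats <- replicate(12, randomCorrMatrix(6), simplify = FALSE)
  dyns <- replicate(12, abs(randomCorrMatrix(6)) / 4, simplify = FALSE)
  y <- rep(0:1, 6)
  a <- fitScreening(mats, dyns, y, M = 2, J = 2, seed = 7, numTrees = 50)
  b <- fitScreening(mats, dyns, y, M = 2, J = 2, seed = 7, numTrees = 50)
  expect_identical(a@staticIdx, b@staticIdx)
  expect_identical(a@dynamicIdx, b@dynamicIdx)
})

test_that("screening rejects single-class labels and out-of-range M", {
  set.seed(3)
  mats <- replicate(6, randomCorrMatrix(5), simplify = FALSE)
  expect_error(fitScreening(mats, NULL, rep(1, 6), M = 2, J = 0, seed = 1),
               "both classes")
  expect_error(fitScreening(mats, NULL, rep(0:1, 3), M = 5, J = 0, seed = 1),
               "out of range")
})

test_that("applying a selection picks exactly the chosen entries", {
  staticM <- matrix(seq_len(16), 4, 4)
  dynM <- matrix(seq_len(16) * 10, 4, 4)
  sel <- methods::new("FeatureSelection",
    staticIdx = list(c(2L, 4L), c(3L, 1L), c(1L, 2L), c(3L, 2L)),
    dynamicIdx = list(3L, 4L, 4L, 1L),
    M = 2L, J = 1L, nRois = 4L, seed = 0L)
  out <- applyScreening(staticM, dynM, sel)
  expect_equal(dim(out), c(4, 3))
  expect_equal(out[1, ], c(staticM[1, 2], staticM[1, 4], dynM[1, 3]))
  expect_equal(out[3, ], c(staticM[3, 1], staticM[3, 2], dynM[3, 4]))
})

test_that("atlas mismatches are rejected", {
  set.seed(4)
  mats <- replicate(8, randomCorrMatrix(5), simplify = FALSE)
  sel <- fitScreening(mats, NULL, rep(0:1, 4), M = 2, J = 0, seed = 1,
                      numTrees = 20)
  expect_error(applyScreening(randomCorrMatrix(7), NULL, sel),
               "atlas mismatch")
})

test_that("cross-validation refits screening per fold without test leakage", {
  co <- smallPlantedCohort(nPerClass = 10, nRois = 8, nTimepoints = 80,
                           staticEffect = 0, seed = 5)
  prep <- prepareCohort(co, k = 2, K = 2, useDynamic = FALSE)
  cv <- crossValidate(prep = prep, M = 2, J = 0, folds = 4, seed = 5,
                      config = trainConfig(epochs = 3, seed = 5),
                      numTrees = 50)
  # on pure-noise data, fold-specific training sets give fold-specific picks
  sigs <- vapply(cv$selections, function(s)
    paste(unlist(s@staticIdx), collapse = ","), character(1))
  expect_gt(length(unique(sigs)), 1)
  # folds partition the cohort: each subject held out exactly once
  expect_equal(sort(unique(cv$folds)), 1:4)
  expect_true(all(!is.na(cv$probs)))
})

test_that("selection tables round-trip through disk", {
  set.seed(6)
  mats <- replicate(10, randomCorrMatrix(6), simplify = FALSE)
  dyns <- replicate(10, abs(randomCorrMatrix(6)) / 4, simplify = FALSE)
  sel <- fitScreening(mats, dyns, rep(0:1, 5), M = 3, J = 2, seed = 9,
                      numTrees = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSelection(sel, f)
  back <- readSelection(f, seed = 9L)
  expect_identical(back@staticIdx, sel@staticIdx)
  expect_identical(back@dynamicIdx, sel@dynamicIdx)
  expect_identical(back@M, sel@M)
  expect_identical(back@J, sel@J)
})
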