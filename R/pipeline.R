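#' Run configuration for the end-to-end pipeline
#'
#' Defaults follow the study setting of the method: M = 48 static plus
#' J = 10 dynamic features per ROI, Chebyshev order K = 3, k = 3 graph
#' neighbours, 5-fold cross-validation. Window length and stride are not
#' fixed by the method and default to common dynamic-connectivity practice
#' (30 time points, stride 10).
#'
#' @param M,J features kept per ROI (static/dynamic).
#' @param k graph neighbours per node.
#' @param K Chebyshev polynomial order.
#' @param windowLength,stride sliding-window settings.
#' @param topFraction fraction of output units kept for edge importance.
#' @param folds CV folds.
#' @param epochs,learningRate training settings (see [trainConfig()]).
#' @param seed master seed for the whole run.
#' @param useDynamic include dynamic features (J is forced to 0 when FALSE).
#' @param useSpatial use the spatial graph for phi (functional fallback
#'   when FALSE).
#' @param doLesion run the (expensive) node-lesion analysis?
#' @param numTrees trees per screening forest.
#' @param nBlocks invertible blocks.
#' @param force overwrite existing outputs?
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(M = 48L, J = 10L, k = 3L, K = 3L, windowLength = 30L,
                      stride = 10L, topFraction = 0.10, folds = 5L,
                      epochs = 100L, learningRate = 1e-3, seed = 1L,
                      useDynamic = TRUE, useSpatial = TRUE, doLesion = FALSE,
                      numTrees = 500L, nBlocks = 3L, force = FALSE) {
  stopifnot(M >= 1, J >= 0, k >= 1, K >= 1, windowLength >= 2, stride >= 1,
            topFraction > 0, topFraction <= 1, folds >= 2, epochs >= 1,
            learningRate > 0, numTrees >= 1, nBlocks >= 1)
  if (!useDynamic) J <- 0L
  structure(list(M = as.integer(M), J = as.integer(J), k = as.integer(k),
                 K = as.integer(K), windowLength = as.integer(windowLength),
                 stride = as.integer(stride), topFraction = topFraction,
                 folds = as.integer(folds), epochs = as.integer(epochs),
                 learningRate = learningRate, seed = as.integer(seed),
                 useDynamic = useDynamic, useSpatial = useSpatial,
                 doLesion = doLesion, numTrees = as.integer(numTrees),
                 nBlocks = as.integer(nBlocks), force = force),
            class = "RunConfig")
}

#' Run the full classification-and-interpretation pipeline
#'
#' Connectivity -> graphs -> per-fold screening -> cross-validated training
#' and evaluation -> final model on all subjects -> reconstruction edge
#' importance (-> optional node-lesion analysis). Writes, under `outDir`:
#' `metrics.tsv` (per-fold and aggregate), `selection.tsv` (final
#' feature selection), `importance_edges.tsv`, optionally
#' `importance_nodes.tsv`, a model checkpoint `checkpoint.rds`, and
#' `run_log.txt` stamped with the config hash and seed. Existing outputs
#' are not overwritten unless `config$force` is set.
#'
#' @param config a [runConfig()].
#' @param cohort an in-memory [Cohort-class]; alternatively give the three
#'   paths below to read one from disk.
#' @param manifestPath,dataDir,coordsPath on-disk cohort location (used
#'   when `cohort` is NULL).
#' @param outDir output directory.
#' @return invisibly, a list with `cv` (the [crossValidate()] result),
#'   `model`, `importance`, and `outDir`.
#' @export
runPipeline <- function(config, outDir, cohort = NULL, manifestPath = NULL,
                        dataDir = NULL, coordsPath = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(cohort))
    cohort <- stage("read", readCohort(manifestPath, dataDir, coordsPath))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.txt")
  if (file.exists(logPath) && !config$force)
    stop(sprintf("%s already exists (set force = TRUE to overwrite)", logPath))

  cfgHash <- .hashObject(unclass(config))
  logLines <- c(sprintf("idgcn pipeline run  config_hash=%s  seed=%d",
                        cfgHash, config$seed),
                sprintf("subjects=%d rois=%d sites=%d", nSubjects(cohort),
                        nRois(cohort), length(unique(siteLabels(cohort)))))

  tc <- trainConfig(epochs = config$epochs, learningRate = config$learningRate,
                    seed = config$seed)
  prep <- stage("connectivity+graphs",
                prepareCohort(cohort, config$windowLength, config$stride,
                              config$k, config$K,
                              useDynamic = config$useDynamic && config$J > 0,
                              useSpatial = config$useSpatial))
  cv <- stage("cross-validation",
              .cvEngine(prep, config$M, config$J, config$folds, config$seed,
                        tc, config$nBlocks, config$numTrees))
  for (f in seq_len(config$folds))
    logLines <- c(logLines, sprintf(
      "fold %d: accuracy=%.3f auc=%.3f precision=%.3f recall=%.3f f1=%.3f",
      f, cv$perFold$accuracy[f], cv$perFold$auc[f], cv$perFold$precision[f],
      cv$perFold$recall[f], cv$perFold$f1[f]))
  logLines <- c(logLines, sprintf("mean accuracy=%.3f (sd %.3f)",
                                  cv$mean[["accuracy"]], cv$sd[["accuracy"]]))

  metricsTab <- rbind(
    cv$perFold,
    data.frame(fold = NA, n = sum(cv$perFold$n), TP = NA, TN = NA, FP = NA,
               FN = NA, accuracy = cv$mean[["accuracy"]], auc = cv$mean[["auc"]],
               precision = cv$mean[["precision"]], recall = cv$mean[["recall"]],
               f1 = cv$mean[["f1"]]))
  metricsTab$config_hash <- cfgHash
  utils::write.table(metricsTab, file.path(outDir, "metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # final model on all subjects for interpretation
  sel <- stage("screening", fitScreening(
    prep$static, if (config$J > 0) prep$dynamic else NULL, prep$labels,
    config$M, config$J, seed = .deriveSeed(config$seed, 9),
    numTrees = config$numTrees))
  model <- stage("train", trainIDGCN(prep, sel, config = tc,
                                     nBlocks = config$nBlocks))
  writeSelection(sel, file.path(outDir, "selection.tsv"))
  imp <- stage("interpret",
               edgeImportance(model, prep, topFraction = config$topFraction))
  writeImportance(imp, edgePath = file.path(outDir, "importance_edges.tsv"),
                  roiIds = prep$roiIds)
  if (config$doLesion) {
    les <- stage("lesion", lesionImportance(
      prep, config$M, config$J, config$folds, config$seed, tc,
      config$nBlocks, config$numTrees, baseline = cv))
    writeImportance(les, nodePath = file.path(outDir, "importance_nodes.tsv"))
    imp@nodeScores <- les@nodeScores
  }
  saveRDS(list(model = model, selection = sel, config = unclass(config),
               config_hash = cfgHash),
          file.path(outDir, "checkpoint.rds"))
  writeLines(logLines, logPath)
  message(paste(logLines, collapse = "\n"))
  invisible(list(cv = cv, model = model, importance = imp, outDir = outDir))
}
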