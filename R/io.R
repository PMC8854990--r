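#' Write a cohort to a directory of plain-text tables
#'
#' Layout: `manifest.tsv` (subject_id, label, site), `coords.tsv` (roi_id,
#' x, y, z), one `<subject_id>_timeseries.tsv` per subject (rows = time
#' points, header = ROI ids), and `ground_truth_edges.tsv` (roi_i, roi_j)
#' when the cohort carries planted edges. All tables are tab-separated.
#'
#' @param cohort a [Cohort-class] with raw time series.
#' @param dir output directory (created if needed).
#' @param force overwrite an existing manifest?
#' @return invisibly, the manifest data.frame.
#' @export
writeCohort <- function(cohort, dir, force = FALSE) {
  stopifnot(methods::is(cohort, "Cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifestPath <- file.path(dir, "manifest.tsv")
  if (file.exists(manifestPath) && !force)
    stop(sprintf("%s already exists (use force = TRUE to overwrite)", manifestPath))
  n <- nSubjects(cohort)
  ids <- sprintf("sub%03d", seq_len(n))
  manifest <- data.frame(subject_id = ids, label = subjectLabels(cohort),
                         site = siteLabels(cohort))
  utils::write.table(manifest, manifestPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  # %.17g keeps doubles exact under write/read round trips
  fmt <- function(m) {
    out <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    colnames(out) <- colnames(m)
    out
  }
  coords <- data.frame(roi_id = cohort@roiIds, fmt(roiCoords(cohort)))
  colnames(coords) <- c("roi_id", "x", "y", "z")
  utils::write.table(coords, file.path(dir, "coords.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (s in seq_len(n)) {
    ts <- cohort@series[[s]]
    if (is.null(ts)) stop(sprintf("subject %s has no raw time series", ids[s]))
    utils::write.table(fmt(ts),
                       file.path(dir, paste0(ids[s], "_timeseries.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (nrow(truthEdges(cohort))) {
    te <- as.data.frame(truthEdges(cohort))
    colnames(te) <- c("roi_i", "roi_j")
    utils::write.table(te, file.path(dir, "ground_truth_edges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(manifest)
}

#' Read a cohort from disk
#'
#' Reads the layout written by [writeCohort()]: a subject manifest, one
#' time-series table per subject, and the ROI coordinates table. Validates
#' binary labels, file presence, and a consistent ROI count across subjects
#' and coordinates, naming the offending subject on failure. A
#' `ground_truth_edges.tsv` sidecar in `dataDir` is picked up when present.
#'
#' @param manifestPath manifest table (subject_id, label, site).
#' @param dataDir directory with `<subject_id>_timeseries.tsv` files.
#' @param coordsPath ROI coordinate table (roi_id, x, y, z).
#' @return a [Cohort-class].
#' @export
readCohort <- function(manifestPath, dataDir, coordsPath) {
  for (p in c(manifestPath, coordsPath))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  manifest <- utils::read.delim(manifestPath)
  need <- c("subject_id", "label", "site")
  if (!all(need %in% colnames(manifest)))
    stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  if (!all(manifest$label %in% c(0, 1)))
    stop(sprintf("non-binary label for subject %s",
                 manifest$subject_id[which(!manifest$label %in% c(0, 1))[1]]))
  coordsTab <- utils::read.delim(coordsPath)
  coords <- as.matrix(coordsTab[, c("x", "y", "z")])
  rownames(coords) <- coordsTab$roi_id
  N <- nrow(coords)
  series <- vector("list", nrow(manifest))
  for (s in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[s]
    f <- file.path(dataDir, paste0(id, "_timeseries.tsv"))
    if (!file.exists(f)) stop(sprintf("missing time-series file for subject %s", id))
    ts <- as.matrix(utils::read.delim(f))
    if (ncol(ts) != N)
      stop(sprintf("subject %s has %d ROIs but the atlas has %d", id, ncol(ts), N))
    series[[s]] <- ts
  }
  tePath <- file.path(dataDir, "ground_truth_edges.tsv")
  te <- if (file.exists(tePath)) {
    t_ <- utils::read.delim(tePath)
    matrix(as.integer(c(t_$roi_i, t_$roi_j)), ncol = 2,
           dimnames = list(NULL, c("i", "j")))
  } else matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j")))
  methods::new("Cohort", series = series, connectivity = list(),
               labels = as.integer(manifest$label),
               sites = as.character(manifest$site), coords = coords,
               roiIds = as.character(coordsTab$roi_id), truthEdges = te,
               spec = list())
}

#' Write a connectivity matrix as delimited text
#'
#' @param C N x N matrix with ROI-id dimnames.
#' @param path output file; written tab-separated with the ROI ids as both
#'   header row and first column.
#' @return invisibly, NULL
#' @export
writeConnectivity <- function(C, path) {
  df <- data.frame(roi_id = rownames(C) %||% seq_len(nrow(C)), C)
  colnames(df) <- c("roi_id", colnames(C) %||% paste0("roi", seq_len(ncol(C))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
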