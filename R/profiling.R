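#' Aggregate per-cell marker signals from an aligned image stack
#'
#' For every instance label and marker image, the mean pixel intensity over
#' the cell's pixel set is recorded together with the cell's area and
#' centroid.
#'
#' @param instances integer instance label matrix (0 = background).
#' @param aligned_stack named list of marker images (aligned, pre-processed),
#'   all the same shape as \code{instances}.
#' @param fov FOV id stored with each cell.
#' @param cell_id_offset added to instance labels to form globally unique
#'   cell ids when tables from several FOVs are combined.
#' @return a [SingleCellTable-class] in the \code{raw} transform state.
#' @export
aggregateCellSignals <- function(instances, aligned_stack, fov = 1L,
                                 cell_id_offset = 0L) {
  for (m in names(aligned_stack))
    if (!identical(dim(aligned_stack[[m]]), dim(instances)))
      stop("marker image '", m, "' and instance map differ in shape")
  labs <- as.vector(instances)
  K <- max(labs)
  if (K == 0) stop("no cells in the instance map")
  inside <- labs > 0
  flab <- labs[inside]
  area <- tabulate(flab, nbins = K)
  if (any(area == 0)) stop("instance labels must be contiguous 1..K")
  rows <- rep(seq_len(nrow(instances)), ncol(instances))[inside]
  cols <- rep(seq_len(ncol(instances)), each = nrow(instances))[inside]
  intensity <- vapply(names(aligned_stack), function(m) {
    v <- as.vector(aligned_stack[[m]])[inside]
    as.numeric(rowsum(v, flab)) / area
  }, numeric(K))
  cellData <- data.frame(
    cell_id = seq_len(K) + cell_id_offset,
    fov = fov,
    area = area,
    centroid_row = as.numeric(rowsum(rows, flab)) / area,
    centroid_col = as.numeric(rowsum(cols, flab)) / area)
  SingleCellTable(t(intensity), cellData, transformState = "raw")
}

#' Combine per-FOV SingleCellTables
#'
#' @param tables list of [SingleCellTable-class] objects with identical
#'   marker panels, all in the raw state.
#' @return one combined [SingleCellTable-class].
#' @export
combineCellTables <- function(tables) {
  stopifnot(length(tables) >= 1)
  mk <- markerNames(tables[[1]])
  for (t in tables)
    if (!identical(markerNames(t), mk) || transformState(t) != "raw")
      stop("tables must share one marker panel and be in the raw state")
  intensity <- do.call(cbind, lapply(tables, intensityMatrix))
  cellData <- do.call(rbind, lapply(tables, function(t)
    as.data.frame(SummarizedExperiment::colData(t))))
  cellData$cell_id <- seq_len(nrow(cellData))
  SingleCellTable(intensity, cellData, transformState = "raw")
}

#' Remove high-intensity outlier cells by MAD
#'
#' A cell is dropped when, for any marker, its value exceeds
#' \code{median + k * MAD} of that marker (high side only). The MAD is the
#' median of absolute deviations from the median (unscaled). Markers with
#' MAD = 0 impose no removals.
#'
#' @param table a [SingleCellTable-class] (>= 3 cells).
#' @param k multiplier (default 5).
#' @return the filtered table; removed cell ids in attribute
#'   \code{"removed"}.
#' @export
removeOutliersMAD <- function(table, k = 5) {
  x <- intensityMatrix(table)
  if (ncol(x) < 3) stop("outlier removal needs at least 3 cells")
  drop <- rep(FALSE, ncol(x))
  for (m in seq_len(nrow(x))) {
    v <- x[m, ]
    md <- median(v)
    madv <- median(abs(v - md))
    if (madv == 0) next
    drop <- drop | v > md + k * madv
  }
  removed <- SummarizedExperiment::colData(table)$cell_id[drop]
  out <- table[, !drop]
  out <- methods::as(out, "SingleCellTable")
  md <- S4Vectors::metadata(out)
  attr(out, "removed") <- removed
  out
}

#' Log-transform aggregate intensities
#'
#' \code{x -> ln(x + delta)} with a small pseudocount; allowed only once
#' (explicit raw -> log state transition).
#'
#' @param table a raw-state [SingleCellTable-class].
#' @param delta pseudocount.
#' @return table in the \code{log} state.
#' @export
logTransform <- function(table, delta = 1e-6) {
  if (transformState(table) != "raw")
    stop("logTransform requires a table in the raw state")
  SummarizedExperiment::assay(table, "intensity") <-
    log(intensityMatrix(table) + delta)
  S4Vectors::metadata(table)$transform_state <- "log"
  table
}

#' Marker positivity thresholds
#'
#' Per-marker threshold at 3 standard deviations below the marker's mean
#' over all cells (log scale). An alternative data-driven rule (Otsu split
#' of the log intensities) is available via \code{method = "otsu"}.
#'
#' @param table a log-state [SingleCellTable-class] with >= 2 cells.
#' @param n_sd how many standard deviations below the mean.
#' @param method "sd_below_mean" (default) or "otsu".
#' @return named numeric vector of thresholds.
#' @export
positivityThresholds <- function(table, n_sd = 3,
                                 method = c("sd_below_mean", "otsu")) {
  method <- match.arg(method)
  if (transformState(table) != "log")
    stop("thresholds are computed on the log scale")
  x <- intensityMatrix(table)
  if (ncol(x) < 2) stop("cannot estimate a threshold from a single cell")
  if (method == "sd_below_mean") {
    thr <- apply(x, 1, function(v) mean(v) - n_sd * sd(v))
  } else {
    thr <- apply(x, 1, function(v) {
      rg <- range(v)
      if (diff(rg) == 0) return(rg[1])
      as.numeric(EBImage::otsu(EBImage::Image(matrix(v, 1)), range = rg))
    })
  }
  names(thr) <- markerNames(table)
  thr
}

#' Call per-cell marker positivity
#'
#' A cell is positive for a marker when its (log) intensity is strictly
#' above the marker's threshold.
#'
#' @param table a log-state [SingleCellTable-class].
#' @param thresholds named vector from [positivityThresholds()].
#' @return the table with a cells x markers logical matrix stored in
#'   \code{metadata(table)$positivity}.
#' @export
callPositivity <- function(table, thresholds = positivityThresholds(table)) {
  x <- intensityMatrix(table)
  stopifnot(all(markerNames(table) %in% names(thresholds)))
  pos <- t(x > thresholds[markerNames(table)])
  colnames(pos) <- markerNames(table)
  rownames(pos) <- SummarizedExperiment::colData(table)$cell_id
  S4Vectors::metadata(table)$positivity <- pos
  S4Vectors::metadata(table)$thresholds <- thresholds
  table
}

#' Assign immune phenotypes from a gating rule table
#'
#' Rules are evaluated in table order (most specific first); a cell matches
#' a rule when it is positive for all of the rule's positive markers and
#' negative for all of its negative markers; the first match wins. Cells
#' matching no rule (in particular CD45-negative cells) are labeled
#' \code{"unassigned"}.
#'
#' @param table a [SingleCellTable-class] with positivity computed.
#' @param rules rule table ([phenotypeRuleTable()] by default).
#' @return the table with per-cell labels in \code{colData(table)$phenotype}.
#' @export
assignPhenotypes <- function(table, rules = phenotypeRuleTable()) {
  pos <- positivity(table)
  if (is.null(pos)) stop("positivity must be computed first (callPositivity)")
  missing <- setdiff(rulesMarkers(rules), colnames(pos))
  if (length(missing))
    stop("rules reference markers absent from the panel: ",
         paste(missing, collapse = ", "))
  lab <- rep("unassigned", nrow(pos))
  for (r in seq_len(nrow(rules))) {
    p <- rules$positive[[r]]; n <- rules$negative[[r]]
    hit <- rep(TRUE, nrow(pos))
    for (m in p) hit <- hit & pos[, m]
    for (m in n) hit <- hit & !pos[, m]
    lab[lab == "unassigned" & hit] <- rules$name[r]
  }
  SummarizedExperiment::colData(table)$phenotype <- lab
  table
}

#' Per-marker z-scored cell matrix
#'
#' Standardizes each marker over cells: \code{(x - mean) / sd}; markers with
#' zero variance map to all zeros.
#'
#' @param table a log-state [SingleCellTable-class].
#' @return cells x markers numeric matrix.
#' @export
zscoreMatrix <- function(table) {
  if (transformState(table) != "log")
    stop("z-scores are computed on the log scale")
  x <- intensityMatrix(table)
  z <- apply(x, 1, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  rownames(z) <- SummarizedExperiment::colData(table)$cell_id
  z
}

#' Write a SingleCellTable to CSV
#'
#' One row per cell: cell_id, fov, area, centroid, one column per marker,
#' and phenotype when assigned.
#' @param table a [SingleCellTable-class].
#' @param path output file.
#' @return path, invisibly.
#' @export
writeCellTable <- function(table, path) {
  utils::write.csv(asCellFrame(table), path, row.names = FALSE)
  invisible(path)
}
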