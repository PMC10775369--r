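#' @import methods
#' @importFrom stats median quantile sd mad rnorm runif fft dist hclust dnorm
#' @importFrom utils head read.csv write.csv
NULL

#' CyclicDataset: an indexed collection of cyclic mIF images
#'
#' Container for a cyclic multiplexed immunofluorescence acquisition: for
#' every (field of view \code{i}, staining cycle \code{j}, channel \code{c})
#' triple it holds a stain image and the paired quenched-background image,
#' together with the marker-panel manifest mapping (cycle, channel) to a
#' marker name.
#'
#' Images are stored as numeric matrices (row, col) in acquisition units
#' (16-bit native) or on the unit interval after percentile normalization.
#'
#' @slot images named list; element \code{"f<i>_c<j>_ch<c>"} is a
#'   \code{list(stain = matrix, quench = matrix)}.
#' @slot manifest \code{data.frame} with columns \code{cycle}, \code{channel},
#'   \code{marker}; marker names are unique across the panel.
#' @slot nFov,nCycles,nChannels integer dimensions M, N, C.
#' @slot normalized logical; \code{TRUE} once preprocessed to [0, 1].
#'
#' @aliases CyclicDataset
#' @export
setClass("CyclicDataset",
  representation(
    images    = "list",
    manifest  = "data.frame",
    nFov      = "integer",
    nCycles   = "integer",
    nChannels = "integer",
    normalized = "logical"
  ),
  prototype(normalized = FALSE)
)

imageKey <- function(fov, cycle, channel) {
  sprintf("f%02d_c%02d_ch%d", fov, cycle, channel)
}

setValidity("CyclicDataset", function(object) {
  M <- object@nFov; N <- object@nCycles; C <- object@nChannels
  if (length(M) != 1L || length(N) != 1L || length(C) != 1L)
    return("dimensions must be scalar")
  keys <- character(0)
  for (i in seq_len(M)) for (j in seq_len(N)) for (c in seq_len(C))
    keys <- c(keys, imageKey(i, j, c))
  missing <- setdiff(keys, names(object@images))
  if (length(missing))
    return(paste0("missing image triples: ",
                  paste(utils::head(missing, 5L), collapse = ", ")))
  for (k in keys) {
    el <- object@images[[k]]
    if (!is.list(el) || !all(c("stain", "quench") %in% names(el)))
      return(paste0("element ", k, " lacks stain/quench pair"))
  }
  mf <- object@manifest
  if (!all(c("cycle", "channel", "marker") %in% names(mf)))
    return("manifest must have cycle, channel, marker columns")
  if (anyDuplicated(mf$marker))
    return("marker names must be unique across the panel")
  # all images within one FOV share a shape
  for (i in seq_len(M)) {
    dims <- unique(lapply(keys[startsWith(keys, sprintf("f%02d_", i))],
                          function(k) dim(object@images[[k]]$stain)))
    if (length(dims) > 1L)
      return(sprintf("FOV %d images differ in shape", i))
  }
  if (any(vapply(object@images, function(el)
        min(el$stain, na.rm = TRUE) < 0 || min(el$quench, na.rm = TRUE) < 0,
        logical(1))))
    return("negative pixel intensities are not allowed")
  TRUE
})

#' Construct a CyclicDataset from in-memory images
#'
#' @param images named list keyed \code{"f<ii>_c<jj>_ch<c>"} of
#'   \code{list(stain=, quench=)} matrices (see [imageKey()] for the exact
#'   format produced by the package).
#' @param manifest data.frame with columns cycle, channel, marker.
#' @param nFov,nCycles,nChannels dataset dimensions M, N, C.
#' @param normalized whether images are already on the unit interval.
#' @return a [CyclicDataset-class] object.
#' @export
CyclicDataset <- function(images, manifest, nFov, nCycles, nChannels,
                          normalized = FALSE) {
  new("CyclicDataset", images = images, manifest = manifest,
      nFov = as.integer(nFov), nCycles = as.integer(nCycles),
      nChannels = as.integer(nChannels), normalized = normalized)
}

#' @describeIn CyclicDataset number of fields of view (M)
#' @param x,object a CyclicDataset
#' @export
nFov <- function(x) x@nFov

#' @describeIn CyclicDataset number of staining cycles (N)
#' @export
nCycles <- function(x) x@nCycles

#' @describeIn CyclicDataset number of channels per cycle (C)
#' @export
nChannels <- function(x) x@nChannels

#' @describeIn CyclicDataset the marker-panel manifest
#' @export
markerManifest <- function(x) x@manifest

#' Retrieve one image from a CyclicDataset
#'
#' @param x a [CyclicDataset-class].
#' @param fov,cycle,channel 1-based indices.
#' @param kind `"stain"` or `"quench"`.
#' @return numeric matrix of pixel intensities.
#' @export
getImage <- function(x, fov, cycle, channel, kind = c("stain", "quench")) {
  kind <- match.arg(kind)
  key <- imageKey(fov, cycle, channel)
  el <- x@images[[key]]
  if (is.null(el)) stop("no image for (", fov, ", ", cycle, ", ", channel, ")")
  el[[kind]]
}

#' Look up the marker imaged at a (cycle, channel) slot
#' @param x a [CyclicDataset-class].
#' @param cycle,channel 1-based indices.
#' @return marker name (character).
#' @export
markerAt <- function(x, cycle, channel) {
  mf <- x@manifest
  hit <- mf$marker[mf$cycle == cycle & mf$channel == channel]
  if (!length(hit)) stop("no marker at cycle ", cycle, " channel ", channel)
  hit
}

setMethod("show", "CyclicDataset", function(object) {
  d <- dim(object@images[[1L]]$stain)
  cat("CyclicDataset:", object@nFov, "FOV x", object@nCycles, "cycles x",
      object@nChannels, "channels\n")
  cat("  image shape:", d[1], "x", d[2],
      if (object@normalized) "(normalized)" else "(raw)", "\n")
  cat("  markers:", paste(object@manifest$marker, collapse = ", "), "\n")
})

#' RegistrationResult: per-cycle translation estimates
#'
#' One row per staining cycle: the trial shifts measured by masked
#' cross-correlation, the final averaged shift at full resolution, a failure
#' flag with reason, and the number of cell-sized anchor objects found.
#'
#' @slot shifts N x 2 numeric matrix (dy, dx) at full resolution; rows are
#'   cycles. The reference cycle's row is (0, 0). Rows of failed cycles
#'   are NA.
#' @slot trialShifts list of per-cycle matrices (one row per surviving trial,
#'   columns dy, dx, at downsampled resolution).
#' @slot failed logical vector per cycle.
#' @slot reason character vector per cycle ("" when not failed).
#' @slot objectsFound integer vector per cycle.
#' @slot referenceCycle 1-based index of the reference cycle.
#'
#' @export
setClass("RegistrationResult",
  representation(
    shifts        = "matrix",
    trialShifts   = "list",
    failed        = "logical",
    reason        = "character",
    objectsFound  = "integer",
    referenceCycle = "integer"
  )
)

setValidity("RegistrationResult", function(object) {
  n <- nrow(object@shifts)
  if (ncol(object@shifts) != 2L) return("shifts must have 2 columns (dy, dx)")
  if (length(object@failed) != n || length(object@reason) != n ||
      length(object@objectsFound) != n)
    return("per-cycle vectors must match the number of cycles")
  r <- object@referenceCycle
  if (r < 1L || r > n) return("referenceCycle out of range")
  if (!object@failed[r] && any(object@shifts[r, ] != 0))
    return("reference cycle shift must be (0, 0)")
  if (any(!object@failed & !is.finite(object@shifts[, 1])))
    return("final shift must be defined for non-failed cycles")
  TRUE
})

#' @describeIn RegistrationResult final per-cycle shifts (N x 2, dy/dx)
#' @param x,object a RegistrationResult
#' @export
cycleShifts <- function(x) x@shifts

#' @describeIn RegistrationResult logical failure flags per cycle
#' @export
registrationFailed <- function(x) x@failed

setMethod("show", "RegistrationResult", function(object) {
  cat("RegistrationResult for", nrow(object@shifts), "cycles (reference =",
      object@referenceCycle, ")\n")
  for (j in seq_len(nrow(object@shifts))) {
    if (object@failed[j]) {
      cat(sprintf("  cycle %d: FAILED (%s)\n", j, object@reason[j]))
    } else {
      cat(sprintf("  cycle %d: dy=%+g dx=%+g (%d objects)\n", j,
                  object@shifts[j, 1], object@shifts[j, 2],
                  object@objectsFound[j]))
    }
  }
})

#' SingleCellTable: cells-by-markers single-cell profiles
#'
#' A \linkS4class{SummarizedExperiment} whose assay \code{"intensity"} holds
#' the markers x cells matrix of mean per-cell fluorescence; \code{colData}
#' carries per-cell metadata (cell id, FOV, area in pixels^2, centroid).
#' The table moves through an explicit transform state machine
#' (\code{raw -> log -> zscore}); positivity calls and phenotype labels are
#' attached by [callPositivity()] and [assignPhenotypes()].
#'
#' @export
setClass("SingleCellTable", contains = "SummarizedExperiment")

setValidity("SingleCellTable", function(object) {
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("cell_id", "fov", "area", "centroid_row", "centroid_col")
  if (!all(need %in% names(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  if (any(cd$area <= 0)) return("cell areas must be positive")
  st <- S4Vectors::metadata(object)$transform_state
  if (is.null(st) || !st %in% c("raw", "log", "zscore"))
    return("metadata transform_state must be raw, log or zscore")
  TRUE
})

#' Construct a SingleCellTable
#'
#' @param intensity markers x cells numeric matrix (rownames = marker names).
#' @param cellData data.frame with one row per cell: cell_id, fov, area,
#'   centroid_row, centroid_col.
#' @param transformState one of "raw", "log", "zscore".
#' @return a [SingleCellTable-class].
#' @export
SingleCellTable <- function(intensity, cellData,
                            transformState = "raw") {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = S4Vectors::DataFrame(cellData))
  md <- list(transform_state = transformState)
  S4Vectors::metadata(se) <- md
  new("SingleCellTable", se)
}

#' @describeIn SingleCellTable ordered marker names
#' @param x,object a SingleCellTable
#' @export
markerNames <- function(x) rownames(SummarizedExperiment::assay(x, "intensity"))

#' @describeIn SingleCellTable current transform state
#' @export
transformState <- function(x) S4Vectors::metadata(x)$transform_state

#' @describeIn SingleCellTable markers x cells intensity matrix
#' @export
intensityMatrix <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @describeIn SingleCellTable cells x markers positivity matrix (or NULL)
#' @export
positivity <- function(x) S4Vectors::metadata(x)$positivity

#' @describeIn SingleCellTable per-cell phenotype labels (or NULL)
#' @export
phenotypes <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("phenotype" %in% names(cd)) cd$phenotype else NULL
}

setMethod("show", "SingleCellTable", function(object) {
  cat("SingleCellTable:", ncol(object), "cells x", nrow(object), "markers",
      sprintf("[%s]\n", transformState(object)))
  cat("  markers:", paste(utils::head(markerNames(object), 8L),
                          collapse = ", "),
      if (nrow(object) > 8L) "..." else "", "\n")
  if (!is.null(positivity(object))) cat("  positivity: computed\n")
  ph <- phenotypes(object)
  if (!is.null(ph)) {
    tb <- sort(table(ph), decreasing = TRUE)
    cat("  phenotypes:", paste(sprintf("%s (%d)", names(tb), tb),
                               collapse = ", "), "\n")
  }
})

#' Export a SingleCellTable as a plain data.frame
#'
#' One row per cell: cell_id, fov, area, centroid, one column per marker,
#' and phenotype when assigned.
#' @param x a [SingleCellTable-class].
#' @return data.frame.
#' @export
asCellFrame <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  m <- t(intensityMatrix(x))
  out <- cbind(cd[, c("cell_id", "fov", "area", "centroid_row",
                      "centroid_col")], as.data.frame(m))
  if (!is.null(phenotypes(x))) out$phenotype <- phenotypes(x)
  rownames(out) <- NULL
  out
}
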