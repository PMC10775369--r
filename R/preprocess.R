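#' Group raw image files into a CyclicDataset
#'
#' Scans TIFF files and groups them by (FOV, cycle, channel, kind) using a
#' configurable Perl regular expression with named capture groups
#' \code{fov}, \code{cycle}, \code{channel} and \code{kind}
#' ("stain"/"quench"). The default pattern matches the naming convention of
#' [writeDataset()].
#'
#' @param file_paths character vector of image paths (or a single directory,
#'   which is scanned for .tif/.tiff files).
#' @param naming_pattern Perl regex with the four named groups, applied to
#'   basenames.
#' @param manifest optional data.frame(cycle, channel, marker); defaults to
#'   [defaultManifest()] over the discovered grid.
#' @param scale multiply raw pixel values by this factor (TIFFs are read on
#'   [0, 1]; keep 1 to stay on the unit scale).
#' @return a [CyclicDataset-class]. Files matching no pattern are reported in
#'   attribute \code{"skipped"}; an incomplete (fov, cycle, channel) grid is
#'   an error naming the missing triples.
#' @export
groupImages <- function(file_paths,
    naming_pattern = "_f(?<fov>\\d+)_c(?<cycle>\\d+)_ch(?<channel>\\d+)_(?<kind>stain|quench)\\.tiff?$",
    manifest = NULL, scale = 1) {
  if (length(file_paths) == 1L && dir.exists(file_paths))
    file_paths <- list.files(file_paths, pattern = "\\.tiff?$",
                             full.names = TRUE)
  m <- regexpr(naming_pattern, basename(file_paths), perl = TRUE)
  skipped <- file_paths[m == -1L]
  keep <- file_paths[m != -1L]
  if (!length(keep)) stop("no files matched the naming pattern")
  st <- attr(m, "capture.start")[m != -1L, , drop = FALSE]
  ln <- attr(m, "capture.length")[m != -1L, , drop = FALSE]
  grab <- function(field)
    substr(basename(keep), st[, field], st[, field] + ln[, field] - 1L)
  info <- data.frame(path = keep,
                     fov = as.integer(grab("fov")),
                     cycle = as.integer(grab("cycle")),
                     channel = as.integer(grab("channel")),
                     kind = grab("kind"), stringsAsFactors = FALSE)
  M <- max(info$fov); N <- max(info$cycle); C <- max(info$channel)
  images <- list()
  missing <- character(0)
  for (i in seq_len(M)) for (j in seq_len(N)) for (c in seq_len(C)) {
    pair <- list()
    for (kind in c("stain", "quench")) {
      hit <- info$path[info$fov == i & info$cycle == j &
                       info$channel == c & info$kind == kind]
      if (length(hit) != 1L) {
        missing <- c(missing, sprintf("(%d,%d,%d,%s)", i, j, c, kind))
      } else {
        pair[[kind]] <- tiff::readTIFF(hit) * scale
      }
    }
    images[[imageKey(i, j, c)]] <- pair
  }
  if (length(missing))
    stop("incomplete image grid; missing (fov,cycle,channel,kind): ",
         paste(missing, collapse = " "))
  if (is.null(manifest)) manifest <- defaultManifest(N, C)
  ds <- CyclicDataset(images, manifest, M, N, C)
  attr(ds, "skipped") <- skipped
  ds
}

#' Subtract the quenched background from a stain image
#'
#' Pixel-by-pixel subtraction of the quench exposure from the matching stain
#' exposure, clipped at zero.
#'
#' @param stain,quench numeric matrices of equal shape.
#' @return matrix \code{pmax(stain - quench, 0)}.
#' @export
subtractBackground <- function(stain, quench) {
  if (!identical(dim(stain), dim(quench)))
    stop("stain and quench images differ in shape")
  pmax(stain - quench, 0)
}

#' Percentile normalization of an image
#'
#' Rescales intensities using the image's own percentiles as lower/upper
#' limits: \code{clip((x - P_low) / (P_high - P_low), 0, 1)}. Defaults are
#' the 25th and 99th percentiles.
#'
#' @param img numeric matrix.
#' @param p_low,p_high percentile limits in [0, 100].
#' @return matrix on [0, 1]. A flat image (P_high == P_low) maps to all
#'   zeros with a warning.
#' @export
normalizePercentile <- function(img, p_low = 25, p_high = 99) {
  stopifnot(length(img) > 0)
  q <- quantile(img, c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("flat image: upper and lower percentiles coincide")
    return(matrix(0, nrow(img), ncol(img)))
  }
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Gaussian denoising with reflected borders
#'
#' Separable Gaussian filter (kernel radius \code{ceiling(3.5 sigma)},
#' normalized to unit mass) with mirror padding, so constant images are
#' unchanged and interior point masses are conserved. \code{sigma = 0} is
#' the identity.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian sd in pixels (>= 0).
#' @return filtered matrix, same shape.
#' @export
gaussianDenoise <- function(img, sigma = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(img)
  r <- ceiling(3.5 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  reflectIdx <- function(n) {
    idx <- c(rev(seq_len(min(r, n))), seq_len(n),
             n + 1 - rev(seq_len(min(r, n))))
    if (r > n) stop("sigma too large for image size")
    idx
  }
  convAxis <- function(x, along) {
    n <- if (along == 1) nrow(x) else ncol(x)
    idx <- reflectIdx(n)
    if (along == 1) {
      xp <- x[idx, , drop = FALSE]
      out <- matrix(0, nrow(x), ncol(x))
      for (t in seq_along(k))
        out <- out + k[t] * xp[seq_len(nrow(x)) + (t - 1L), , drop = FALSE]
    } else {
      xp <- x[, idx, drop = FALSE]
      out <- matrix(0, nrow(x), ncol(x))
      for (t in seq_along(k))
        out <- out + k[t] * xp[, seq_len(ncol(x)) + (t - 1L), drop = FALSE]
    }
    out
  }
  convAxis(convAxis(img, 1), 2)
}

#' Pre-process every image of a CyclicDataset
#'
#' Applies the fixed pixel-level pipeline to each (FOV, cycle, channel)
#' stain image: quench subtraction, then percentile normalization, then
#' Gaussian denoising. Quench images are consumed by the subtraction and
#' replaced by zero matrices in the output (their information is spent).
#'
#' @param dataset a [CyclicDataset-class] of raw images.
#' @param p_low,p_high percentile limits (see [normalizePercentile()]).
#' @param sigma Gaussian sd in px; 0 disables denoising.
#' @param .trace internal: function called with the stage name before each
#'   step (used to verify stage order).
#' @return a normalized [CyclicDataset-class].
#' @export
preprocessDataset <- function(dataset, p_low = 25, p_high = 99, sigma = 1,
                              .trace = NULL) {
  images <- dataset@images
  for (key in names(images)) {
    el <- images[[key]]
    if (!is.null(.trace)) .trace("subtract")
    x <- subtractBackground(el$stain, el$quench)
    if (!is.null(.trace)) .trace("normalize")
    x <- suppressWarnings(normalizePercentile(x, p_low, p_high))
    if (!is.null(.trace)) .trace("denoise")
    x <- gaussianDenoise(x, sigma)
    images[[key]] <- list(stain = x, quench = matrix(0, nrow(x), ncol(x)))
  }
  out <- CyclicDataset(images, dataset@manifest, dataset@nFov,
                       dataset@nCycles, dataset@nChannels, normalized = TRUE)
  out
}
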