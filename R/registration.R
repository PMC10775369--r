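#' Registration configuration
#'
#' Parameters of the per-cycle translation estimator: images are
#' maximum-projected over channels, foreground-masked, downsampled, and the
#' translation measured by masked normalized cross-correlation on
#' \code{n_trials} random crops whose surviving shifts are averaged.
#'
#' @param reference_cycle 1-based cycle all others are aligned to.
#' @param downsample_factor linear rescale before correlation (0.5 = 2x2
#'   block mean).
#' @param crop_factor random crop per axis on each trial (0 < f <= 1).
#' @param n_trials number of random-crop trials t.
#' @param outlier_distance trials farther than this (px, downsampled
#'   Euclidean) from the component-wise trial median are discarded.
#' @param min_objects minimum number of cell-sized foreground objects
#'   required in both images; below it the cycle fails ("low cellularity").
#' @param size_band c(a_min, a_max) connected-component area band (px^2,
#'   full resolution) defining "cell-sized".
#' @param seed RNG seed for the crop windows.
#' @return config list (class "mifRegistrationConfig").
#' @export
registrationConfig <- function(reference_cycle = 1L, downsample_factor = 0.5,
                               crop_factor = 0.75, n_trials = 3L,
                               outlier_distance = 4, min_objects = 5L,
                               size_band = c(30, 5000), seed = 1L) {
  stopifnot(crop_factor > 0, crop_factor <= 1, n_trials >= 1,
            size_band[1] < size_band[2])
  structure(list(reference_cycle = as.integer(reference_cycle),
                 downsample_factor = downsample_factor,
                 crop_factor = crop_factor, n_trials = as.integer(n_trials),
                 outlier_distance = outlier_distance,
                 min_objects = as.integer(min_objects),
                 size_band = size_band, seed = as.integer(seed)),
            class = "mifRegistrationConfig")
}

#' Maximum projection across channel images
#'
#' Collapses the C channel images of one cycle into a single image by the
#' per-pixel maximum, pooling anchoring cells that may be visible in one
#' channel but not another.
#'
#' @param channel_images non-empty list of equal-shape matrices.
#' @return matrix of per-pixel maxima.
#' @export
maxProject <- function(channel_images) {
  if (!length(channel_images)) stop("no channel images to project")
  Reduce(pmax, channel_images)
}

#' Foreground mask of cell-sized objects
#'
#' Otsu threshold on a normalized image, morphological opening with a 3x3
#' box, connected-component labeling, and retention of components whose
#' area lies in \code{size_band}.
#'
#' @param img normalized matrix (values in [0, 1]).
#' @param size_band c(a_min, a_max) area band in px^2.
#' @return list(mask = logical matrix, count = number of retained objects).
#' @export
foregroundMask <- function(img, size_band = c(30, 5000)) {
  if (max(img) <= min(img))
    return(list(mask = matrix(FALSE, nrow(img), ncol(img)), count = 0L))
  thr <- EBImage::otsu(EBImage::Image(img), range = range(img))
  bin <- img > thr
  opened <- EBImage::opening(EBImage::Image(bin * 1),
                             EBImage::makeBrush(3, "box"))
  lab <- EBImage::bwlabel(opened)
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0)
    return(list(mask = matrix(FALSE, nrow(img), ncol(img)), count = 0L))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= size_band[1] & areas <= size_band[2])
  list(mask = matrix(lab %in% keep, nrow(img), ncol(img)),
       count = length(keep))
}

# 2x2 block-mean downsample (odd trailing row/col dropped)
.blockMean2 <- function(x) {
  nr <- (nrow(x) %/% 2L) * 2L; nc <- (ncol(x) %/% 2L) * 2L
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  (x[seq(1, nr, 2), seq(1, nc, 2)] + x[seq(2, nr, 2), seq(1, nc, 2)] +
   x[seq(1, nr, 2), seq(2, nc, 2)] + x[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

.downsample <- function(img, factor) {
  if (factor == 1) return(img)
  if (abs(factor - 0.5) > 1e-12)
    stop("only downsample factors 1 and 0.5 are supported")
  .blockMean2(img)
}

.downsampleMask <- function(mask, factor) {
  if (factor == 1) return(mask)
  .blockMean2(mask * 1) > 0
}

# Masked normalized cross-correlation (Padfield), Fourier-accelerated.
# Returns the integer translation s = (dy, dx) such that
# moving(x) ~ reference(x - s), i.e. content displaced by +s.
.maskedNCCShift <- function(ref, mov, refMask, movMask,
                            overlap_ratio = 0.3) {
  d1 <- dim(ref); d2 <- dim(mov)
  P <- c(stats::nextn(d1[1] + d2[1] - 1L, c(2, 3, 5)),
         stats::nextn(d1[2] + d2[2] - 1L, c(2, 3, 5)))
  pad <- function(x) {
    out <- matrix(0, P[1], P[2])
    out[seq_len(nrow(x)), seq_len(ncol(x))] <- x
    out
  }
  rot <- function(x) x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))), drop = FALSE]
  f1 <- ref * refMask
  f2 <- mov * movMask
  F1  <- fft(pad(f1))
  M1  <- fft(pad(refMask * 1))
  F2r <- fft(pad(rot(f2)))
  M2r <- fft(pad(rot(movMask * 1)))
  F1sq <- fft(pad(f1^2))
  F2rsq <- fft(pad(rot(f2^2)))
  ifftRe <- function(z) Re(fft(z, inverse = TRUE)) / length(z)
  overlap <- ifftRe(M2r * M1)
  overlap <- pmax(round(overlap), 0)
  corrF1 <- ifftRe(M2r * F1)
  corrF2 <- ifftRe(M1 * F2r)
  ok <- overlap > 0
  numerator <- ifftRe(F2r * F1)
  numerator[ok] <- numerator[ok] - corrF1[ok] * corrF2[ok] / overlap[ok]
  numerator[!ok] <- 0
  den1 <- ifftRe(M2r * F1sq); den2 <- ifftRe(M1 * F2rsq)
  den1[ok] <- den1[ok] - corrF1[ok]^2 / overlap[ok]
  den2[ok] <- den2[ok] - corrF2[ok]^2 / overlap[ok]
  den1 <- pmax(den1, 0); den2 <- pmax(den2, 0)
  den1[!ok] <- 0; den2[!ok] <- 0
  denom <- sqrt(den1 * den2)
  xcorr <- matrix(0, P[1], P[2])
  good <- ok & denom > sqrt(.Machine$double.eps) * max(denom)
  xcorr[good] <- numerator[good] / denom[good]
  xcorr[xcorr > 1.1] <- 0 # numerically unstable bins
  minOverlap <- max(1, overlap_ratio * max(overlap))
  xcorr[overlap < minOverlap] <- 0
  # valid correlation lags live in the first (d1 + d2 - 1) rows/cols
  valid <- xcorr[seq_len(d1[1] + d2[1] - 1L), seq_len(d1[2] + d2[2] - 1L),
                 drop = FALSE]
  peak <- which(valid == max(valid), arr.ind = TRUE)[1, ]
  # lag index k (1-based) corresponds to content displacement dim(mov) - k
  c(dy = unname(d2[1] - peak[1]), dx = unname(d2[2] - peak[2]))
}

#' Estimate the translation between two cycle images
#'
#' Both images are maximum projections on the unit scale. Foreground masks
#' of cell-sized objects are computed (unless supplied), images and masks
#' are downsampled, and on each of \code{n_trials} trials a random crop
#' (identical window for image and mask, and for reference and moving) is
#' taken and the masked normalized cross-correlation peak recorded. Trials
#' farther than \code{outlier_distance} from the component-wise trial median
#' are discarded; the mean surviving shift is scaled back to full resolution
#' and rounded to the nearest integer pixel.
#'
#' @param reference,moving max-projected normalized matrices.
#' @param config a [registrationConfig()].
#' @param ref_mask,mov_mask optional precomputed full-resolution masks
#'   (lists as returned by [foregroundMask()]).
#' @return list(trial_shifts, final_shift, failed, reason, objects_found).
#'   \code{final_shift} is (dy, dx) such that \code{moving} is the reference
#'   scene displaced by \code{final_shift}.
#' @export
estimateShift <- function(reference, moving, config = registrationConfig(),
                          ref_mask = NULL, mov_mask = NULL) {
  if (is.null(ref_mask)) ref_mask <- foregroundMask(reference, config$size_band)
  if (is.null(mov_mask)) mov_mask <- foregroundMask(moving, config$size_band)
  objects <- min(ref_mask$count, mov_mask$count)
  fail <- function(reason) list(
    trial_shifts = matrix(numeric(0), 0, 2), final_shift = c(NA_real_, NA_real_),
    failed = TRUE, reason = reason, objects_found = objects)
  if (objects < config$min_objects) return(fail("low cellularity"))

  f <- config$downsample_factor
  refD <- .downsample(reference, f); movD <- .downsample(moving, f)
  rmD <- .downsampleMask(ref_mask$mask, f)
  mmD <- .downsampleMask(mov_mask$mask, f)
  d <- dim(refD)
  win <- pmax(c(8L, 8L), floor(config$crop_factor * d))
  trials <- matrix(NA_real_, config$n_trials, 2)
  for (t in seq_len(config$n_trials)) {
    r0 <- if (d[1] > win[1]) sample.int(d[1] - win[1] + 1L, 1L) else 1L
    c0 <- if (d[2] > win[2]) sample.int(d[2] - win[2] + 1L, 1L) else 1L
    rows <- r0:(r0 + win[1] - 1L); cols <- c0:(c0 + win[2] - 1L)
    if (!any(rmD[rows, cols]) || !any(mmD[rows, cols])) next
    trials[t, ] <- .maskedNCCShift(refD[rows, cols], movD[rows, cols],
                                   rmD[rows, cols], mmD[rows, cols])
  }
  trials <- trials[stats::complete.cases(trials), , drop = FALSE]
  if (!nrow(trials)) return(fail("unstable correlation"))
  med <- apply(trials, 2, median)
  dists <- sqrt((trials[, 1] - med[1])^2 + (trials[, 2] - med[2])^2)
  keep <- trials[dists <= config$outlier_distance, , drop = FALSE]
  if (!nrow(keep)) return(fail("unstable correlation"))
  final <- round(colMeans(keep) / f)
  list(trial_shifts = keep, final_shift = c(dy = final[1], dx = final[2]),
       failed = FALSE, reason = "", objects_found = objects)
}

#' Align all cycles of a dataset from a single field of view
#'
#' One shift per cycle is estimated from the designated FOV's max
#' projections and then assigned to every FOV of that cycle (a single
#' remounting offset applies to the whole slide).
#'
#' @param dataset a normalized [CyclicDataset-class].
#' @param fov_for_alignment 1-based FOV index used for estimation.
#' @param config a [registrationConfig()].
#' @return a [RegistrationResult-class] with one row per cycle.
#' @export
alignCycleSet <- function(dataset, fov_for_alignment = 1L,
                          config = registrationConfig()) {
  if (!dataset@normalized)
    warning("dataset is not normalized; registration expects preprocessed images")
  N <- nCycles(dataset); C <- nChannels(dataset)
  set.seed(config$seed)
  proj <- lapply(seq_len(N), function(j)
    maxProject(lapply(seq_len(C), function(c)
      getImage(dataset, fov_for_alignment, j, c, "stain"))))
  masks <- lapply(proj, foregroundMask, size_band = config$size_band)
  ref <- config$reference_cycle
  shifts <- matrix(0, N, 2, dimnames = list(NULL, c("dy", "dx")))
  trialShifts <- vector("list", N)
  failed <- logical(N); reason <- character(N)
  objects <- integer(N)
  objects[ref] <- masks[[ref]]$count
  trialShifts[[ref]] <- matrix(0, 1, 2)
  for (j in seq_len(N)) {
    if (j == ref) next
    est <- estimateShift(proj[[ref]], proj[[j]], config,
                         ref_mask = masks[[ref]], mov_mask = masks[[j]])
    shifts[j, ] <- est$final_shift
    trialShifts[[j]] <- est$trial_shifts
    failed[j] <- est$failed
    reason[j] <- est$reason
    objects[j] <- est$objects_found
  }
  new("RegistrationResult", shifts = shifts, trialShifts = trialShifts,
      failed = failed, reason = reason, objectsFound = objects,
      referenceCycle = as.integer(ref))
}

#' Translate an image back onto the reference frame
#'
#' Translates the image by \code{-shift} (integer pixels) so that a scene
#' displaced by \code{shift} lands on the reference frame; vacated pixels
#' are zero-filled and the shape is preserved.
#'
#' @param img numeric matrix.
#' @param shift numeric (dy, dx); rounded to integers.
#' @return translated matrix.
#' @export
applyShift <- function(img, shift) {
  s <- round(shift)
  dy <- s[1]; dx <- s[2]
  nr <- nrow(img); nc <- ncol(img)
  if (abs(dy) >= nr || abs(dx) >= nc) return(matrix(0, nr, nc))
  out <- matrix(0, nr, nc)
  # destination rows r receive source rows r + dy
  srcR <- seq_len(nr) + dy; srcC <- seq_len(nc) + dx
  okR <- srcR >= 1 & srcR <= nr; okC <- srcC >= 1 & srcC <= nc
  out[which(okR), which(okC)] <- img[srcR[okR], srcC[okC], drop = FALSE]
  out
}

#' Apply a RegistrationResult to every image of a dataset
#'
#' Each cycle's estimated shift is applied to all of its FOVs and channels.
#' Failed cycles are left untouched and reported in attribute
#' \code{"unaligned_cycles"}.
#'
#' @param dataset a [CyclicDataset-class].
#' @param result a [RegistrationResult-class].
#' @return aligned [CyclicDataset-class].
#' @export
applyShiftToDataset <- function(dataset, result) {
  images <- dataset@images
  sh <- cycleShifts(result)
  for (i in seq_len(nFov(dataset))) for (j in seq_len(nCycles(dataset)))
    for (c in seq_len(nChannels(dataset))) {
      if (registrationFailed(result)[j]) next
      key <- imageKey(i, j, c)
      images[[key]]$stain <- applyShift(images[[key]]$stain, sh[j, ])
    }
  out <- CyclicDataset(images, dataset@manifest, dataset@nFov,
                       dataset@nCycles, dataset@nChannels,
                       normalized = dataset@normalized)
  attr(out, "unaligned_cycles") <- which(registrationFailed(result))
  out
}
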