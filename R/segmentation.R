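#' Loss weights for the composite segmentation objective
#'
#' The training objective is
#' \deqn{L = L_{ce} + \alpha L_{jacc} + \lambda_c L_{count} +
#'       \lambda_a L_{auto} + \beta L_{reg}}
#' combining weighted pixel cross-entropy, soft per-class Jaccard loss, the
#' squared error of the cell-count head, the mean squared error of the
#' auto-encoding head, and L2 weight regularization.
#'
#' Cross-entropy pixels are weighted 3-fold for the cell-interior and
#' cell-boundary classes relative to background, and a further 2-fold when a
#' true boundary pixel is currently predicted as interior (to discourage
#' merging touching cells). Defaults: alpha = 1e3, lambda_c = 1e3,
#' lambda_a = 0.5, beta = 1e-4.
#'
#' @param alpha Jaccard weight.
#' @param lambda_c count-head weight.
#' @param lambda_a auto-encoder weight.
#' @param beta L2 regularization weight.
#' @param class_weights length-3 vector (background, interior, boundary).
#' @param boundary_as_interior_multiplier extra weight on true-boundary
#'   pixels whose current argmax prediction is interior.
#' @return list of validated weights (class "mifLossWeights").
#' @export
lossWeights <- function(alpha = 1e3, lambda_c = 1e3, lambda_a = 0.5,
                        beta = 1e-4, class_weights = c(1, 3, 3),
                        boundary_as_interior_multiplier = 2) {
  w <- list(alpha = alpha, lambda_c = lambda_c, lambda_a = lambda_a,
            beta = beta, class_weights = class_weights,
            boundary_as_interior_multiplier = boundary_as_interior_multiplier)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "mifLossWeights")
}

#' Training configuration for the segmentation network
#'
#' Defaults mirror a full-scale run (300 px tiles with 20% overlap, batch
#' size 16, Adam at 1e-5, 700 epochs); tests and the worked examples use a
#' scaled-down configuration.
#'
#' @param tile_size square tile side in px.
#' @param overlap_fraction fractional overlap between neighboring tiles.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param augment logical; stochastic 90-degree rotation, horizontal and
#'   vertical flips, Gaussian noise and mean shift.
#' @param noise_sd,shift_range augmentation magnitudes (input units).
#' @param validation_fraction fraction of tiles held out (split by FOV when
#'   FOV ids are supplied to [trainNetwork()]).
#' @param seed RNG seed for shuffling and augmentation.
#' @return list (class "mifTrainConfig").
#' @export
trainConfig <- function(tile_size = 300L, overlap_fraction = 0.2,
                        batch_size = 16L, epochs = 700L,
                        learning_rate = 1e-5, augment = TRUE,
                        noise_sd = 0.02, shift_range = 0.05,
                        validation_fraction = 0.2, seed = 1L) {
  stopifnot(tile_size > 0, overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(tile_size = as.integer(tile_size),
                 overlap_fraction = overlap_fraction,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, augment = augment,
                 noise_sd = noise_sd, shift_range = shift_range,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "mifTrainConfig")
}

#' Tile an image with overlap
#'
#' Tiles cover the whole image with stride
#' \code{round(tile_size * (1 - overlap))}; the last tile on each axis is
#' anchored at \code{max(0, dim - tile_size)}. Tiles extending past a small
#' image are zero-padded with their valid extent recorded.
#'
#' @param img numeric matrix.
#' @param tile_size square tile side (px).
#' @param overlap fractional overlap in [0, 1).
#' @return list of \code{list(tile, row_offset, col_offset, valid_rows,
#'   valid_cols)}; offsets are 0-based.
#' @export
tileImage <- function(img, tile_size = 300L, overlap = 0.2) {
  stopifnot(nrow(img) >= 1, ncol(img) >= 1)
  stride <- max(1L, round(tile_size * (1 - overlap)))
  offsets <- function(n) {
    if (n <= tile_size) return(0L)
    off <- seq(0L, n - tile_size, by = stride)
    if (off[length(off)] + tile_size < n) off <- c(off, n - tile_size)
    off
  }
  ro <- offsets(nrow(img)); co <- offsets(ncol(img))
  out <- list()
  for (r in ro) for (c in co) {
    vr <- min(tile_size, nrow(img) - r); vc <- min(tile_size, ncol(img) - c)
    tile <- matrix(0, tile_size, tile_size)
    tile[seq_len(vr), seq_len(vc)] <-
      img[r + seq_len(vr), c + seq_len(vc), drop = FALSE]
    out[[length(out) + 1L]] <- list(tile = tile, row_offset = r,
                                    col_offset = c, valid_rows = vr,
                                    valid_cols = vc)
  }
  out
}

#' Rasterize an instance label map into the three-class mask
#'
#' Ground-truth construction for training: pixels of an instance within
#' \code{boundary_width} (Euclidean) of any differently-labeled pixel
#' (background or neighboring cell) become class 2 (boundary); the remaining
#' instance pixels class 1 (interior); the rest class 0. Interiors of
#' distinct instances are therefore never 4-connected to each other.
#'
#' @param instances integer matrix, 0 = background, k > 0 = cell k.
#' @param boundary_width ring width in px.
#' @return integer matrix with values in \{0, 1, 2\}.
#' @export
rasterizeLabels <- function(instances, boundary_width = 2L) {
  stopifnot(all(instances >= 0))
  nr <- nrow(instances); nc <- ncol(instances)
  mask <- matrix(0L, nr, nc)
  fg <- instances > 0
  if (!any(fg)) return(mask)
  # boundary: a foreground pixel with a differently-labeled pixel within
  # Euclidean distance boundary_width (offsets precomputed)
  offs <- expand.grid(dy = -boundary_width:boundary_width,
                      dx = -boundary_width:boundary_width)
  offs <- offs[offs$dy^2 + offs$dx^2 <= boundary_width^2 &
               !(offs$dy == 0 & offs$dx == 0), ]
  boundary <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    shifted <- matrix(0L, nr, nc) # out-of-frame treated as background
    rS <- seq_len(nr) + dy; cS <- seq_len(nc) + dx
    okR <- rS >= 1 & rS <= nr; okC <- cS >= 1 & cS <= nc
    shifted[which(okR), which(okC)] <-
      instances[rS[okR], cS[okC], drop = FALSE]
    boundary <- boundary | (fg & shifted != instances)
  }
  mask[fg] <- 1L
  mask[boundary] <- 2L
  mask
}

.clampProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1)

#' Weighted pixel cross-entropy
#'
#' Mean over pixels of \code{w(px) * (-log p_true(px))} where \code{w} is the
#' class weight of the true class, multiplied by
#' \code{boundary_as_interior_multiplier} when the true class is boundary and
#' the current argmax prediction is interior. The multiplier is a constant
#' per forward pass (it is not differentiated through).
#'
#' @param pred_probs H x W x 3 array of class probabilities (sums to 1 per
#'   pixel).
#' @param target H x W integer matrix with values in \{0, 1, 2\}.
#' @param weights a [lossWeights()].
#' @return scalar loss.
#' @export
weightedCrossEntropy <- function(pred_probs, target, weights = lossWeights()) {
  stopifnot(length(dim(pred_probs)) == 3, dim(pred_probs)[3] == 3,
            all(dim(pred_probs)[1:2] == dim(target)))
  n <- length(target)
  idx <- cbind(rep(seq_len(nrow(target)), ncol(target)),
               rep(seq_len(ncol(target)), each = nrow(target)),
               as.vector(target) + 1L)
  ptrue <- .clampProb(pred_probs[idx])
  w <- weights$class_weights[as.vector(target) + 1L]
  pm <- apply(pred_probs, c(1, 2), which.max) - 1L
  w <- w * ifelse(as.vector(target) == 2L & as.vector(pm) == 1L,
                  weights$boundary_as_interior_multiplier, 1)
  mean(w * (-log(ptrue)))
}

#' Soft per-class Jaccard loss
#'
#' Mean over the three classes of
#' \code{1 - (sum(p_k y_k) + eps) / (sum(p_k) + sum(y_k) - sum(p_k y_k) + eps)}
#' with probabilistic (soft) intersection and union.
#'
#' @inheritParams weightedCrossEntropy
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
jaccardLoss <- function(pred_probs, target, eps = 1e-7) {
  stopifnot(length(dim(pred_probs)) == 3, dim(pred_probs)[3] == 3)
  loss <- 0
  for (k in 0:2) {
    y <- (target == k) * 1
    p <- pred_probs[, , k + 1L]
    inter <- sum(p * y)
    union <- sum(p) + sum(y) - inter
    loss <- loss + (1 - (inter + eps) / (union + eps))
  }
  loss / 3
}

#' Cell-count and auto-encoding losses
#'
#' \code{countLoss} is the squared error between the count head's prediction
#' and the number of distinct instances intersecting the tile;
#' \code{autoencodeLoss} is the mean squared error between the reconstruction
#' and the input.
#'
#' @param predicted_count scalar prediction.
#' @param instances integer instance map of the tile (or a precomputed count).
#' @return scalar loss.
#' @export
countLoss <- function(predicted_count, instances) {
  n <- if (is.matrix(instances)) length(setdiff(unique(as.vector(instances)), 0L))
       else as.numeric(instances)
  (predicted_count - n)^2
}

#' @rdname countLoss
#' @param reconstruction,input equal-shape arrays.
#' @export
autoencodeLoss <- function(reconstruction, input) {
  stopifnot(identical(dim(reconstruction), dim(input)))
  mean((reconstruction - input)^2)
}

#' Combine loss components into the training objective
#'
#' @param Lce,Ljacc,Lcount,Lauto,Lreg scalar components.
#' @param w a [lossWeights()].
#' @return \code{Lce + alpha Ljacc + lambda_c Lcount + lambda_a Lauto +
#'   beta Lreg}.
#' @export
totalLoss <- function(Lce, Ljacc, Lcount, Lauto, Lreg, w = lossWeights()) {
  stopifnot(all(is.finite(c(Lce, Ljacc, Lcount, Lauto, Lreg))))
  Lce + w$alpha * Ljacc + w$lambda_c * Lcount + w$lambda_a * Lauto +
    w$beta * Lreg
}

#' Convert a three-class mask into per-cell instance labels
#'
#' Connected components of the interior class (4-connectivity) seed the
#' instances; each seed is expanded into adjacent boundary pixels by
#' geodesic (watershed-style) propagation over the foreground; components
#' with final area below \code{min_area} are removed and labels renumbered
#' 1..K.
#'
#' @param mask integer matrix in \{0, 1, 2\}.
#' @param min_area minimum instance area (px^2).
#' @return integer instance label matrix.
#' @export
extractInstances <- function(mask, min_area = 20L) {
  stopifnot(all(mask %in% 0:2))
  interior <- (mask == 1L) * 1
  seeds <- EBImage::imageData(EBImage::bwlabel(interior))
  if (max(seeds) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  fg <- (mask > 0L) * 1
  lab <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(matrix(0, nrow(mask), ncol(mask))), seeds, mask = fg))
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_area)
  matrix(match(lab, keep, nomatch = 0L), nrow(mask), ncol(mask))
}
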